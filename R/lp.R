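#' Solve a bounded linear program
#'
#' Minimises `obj %*% x` subject to `Aeq x = beq`, `Ale x <= ble` and
#' `lb <= x <= ub`. Used internally for all flux-balance style problems.
#' The primary route is an interior ridge-regularised quadratic program
#' (`quadprog::solve.QP` with a ridge small enough that the solution sits on
#' the same vertex as the exact LP); if quadprog reports inconsistent or
#' degenerate constraints a two-phase simplex (`boot::simplex`) fallback on
#' shifted non-negative variables is used.
#'
#' @param obj numeric objective vector (minimised).
#' @param Aeq,beq equality constraints (matrix may have zero rows).
#' @param Ale,ble inequality constraints `Ale x <= ble`.
#' @param lb,ub variable bounds; infinities allowed.
#' @param ridge ridge coefficient for the regularised solve.
#' @return list with `x`, `objective`, `status` ("optimal" or "infeasible").
#' @keywords internal
solve_lp <- function(obj, Aeq = NULL, beq = NULL, Ale = NULL, ble = NULL,
                     lb = NULL, ub = NULL, ridge = 1e-9) {
  n <- length(obj)
  if (is.null(lb)) lb <- rep(-Inf, n)
  if (is.null(ub)) ub <- rep(Inf, n)
  full_Aeq <- Aeq; full_beq <- beq
  if (!is.null(Aeq) && nrow(Aeq) > 1) {
    # quadprog requires linearly independent equality rows
    qrA <- qr(t(Aeq))
    keep <- qrA$pivot[seq_len(qrA$rank)]
    Aeq <- Aeq[keep, , drop = FALSE]
    beq <- beq[keep]
  }
  # quadprog's active-set path can falsely report inconsistency for
  # degenerate problems; retry with larger ridge and a tiny deterministic
  # objective perturbation before falling back to the simplex
  jitter <- 1e-9 * sin(seq_len(n))
  attempts <- list(list(r = ridge, d = -obj),
                   list(r = ridge * 1e3, d = -obj),
                   list(r = ridge * 1e3, d = -obj + jitter),
                   list(r = ridge * 1e6, d = -obj + jitter))
  for (at in attempts) {
    sol <- try(solve_qp_raw(Dmat = diag(2 * at$r, n), dvec = at$d,
                            Aeq = Aeq, beq = beq, Ale = Ale, ble = ble,
                            lb = lb, ub = ub), silent = TRUE)
    if (!inherits(sol, "try-error")) {
      if (!is.null(full_Aeq) &&
          max(abs(full_Aeq %*% sol - full_beq)) > 1e-6) next
      return(list(x = sol, objective = sum(obj * sol), status = "optimal"))
    }
  }
  Aeq <- full_Aeq; beq <- full_beq
  sol2 <- try(solve_lp_simplex(obj, Aeq, beq, Ale, ble, lb, ub), silent = TRUE)
  if (inherits(sol2, "try-error") || is.null(sol2)) {
    return(list(x = rep(NA_real_, n), objective = NA_real_,
                status = "infeasible"))
  }
  sol2
}

#' Solve a convex quadratic program with bounds
#'
#' Minimises `0.5 x' D x - d' x` under equality/inequality constraints and
#' bounds. Thin wrapper over [quadprog::solve.QP()] translating the bound and
#' `<=` conventions.
#'
#' @inheritParams solve_lp
#' @param Dmat positive-definite quadratic term.
#' @param dvec linear term (note quadprog sign convention).
#' @return solution vector; errors if infeasible.
#' @keywords internal
solve_qp_raw <- function(Dmat, dvec, Aeq = NULL, beq = NULL,
                         Ale = NULL, ble = NULL, lb = NULL, ub = NULL) {
  n <- length(dvec)
  cons <- list()
  rhs <- list()
  if (!is.null(Aeq) && nrow(Aeq) > 0) {
    cons[[length(cons) + 1L]] <- Aeq
    rhs[[length(rhs) + 1L]] <- beq
    meq <- nrow(Aeq)
  } else {
    meq <- 0L
  }
  finite_lb <- which(is.finite(lb))
  if (length(finite_lb)) {
    E <- matrix(0, length(finite_lb), n)
    E[cbind(seq_along(finite_lb), finite_lb)] <- 1
    cons[[length(cons) + 1L]] <- E
    rhs[[length(rhs) + 1L]] <- lb[finite_lb]
  }
  finite_ub <- which(is.finite(ub))
  if (length(finite_ub)) {
    E <- matrix(0, length(finite_ub), n)
    E[cbind(seq_along(finite_ub), finite_ub)] <- -1
    cons[[length(cons) + 1L]] <- E
    rhs[[length(rhs) + 1L]] <- -ub[finite_ub]
  }
  if (!is.null(Ale) && nrow(Ale) > 0) {
    cons[[length(cons) + 1L]] <- -Ale
    rhs[[length(rhs) + 1L]] <- -ble
  }
  Amat <- t(do.call(rbind, cons))
  bvec <- unlist(rhs)
  quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = meq)$solution
}

# Pure-LP fallback on shifted non-negative variables (boot::simplex).
# Variables with infinite bounds are boxed at +-BIG; adequate for the small
# toy-scale LPs this package solves when quadprog declines.
solve_lp_simplex <- function(obj, Aeq, beq, Ale, ble, lb, ub, BIG = 1e4) {
  n <- length(obj)
  lb2 <- pmax(lb, -BIG)
  ub2 <- pmin(ub, BIG)
  # y = x - lb2 >= 0, y <= ub2 - lb2
  A1 <- diag(n)
  b1 <- ub2 - lb2
  A3 <- NULL; b3 <- NULL
  if (!is.null(Aeq) && nrow(Aeq) > 0) {
    A3 <- Aeq
    b3 <- beq - as.numeric(Aeq %*% lb2)
    neg <- b3 < 0
    A3[neg, ] <- -A3[neg, , drop = FALSE]
    b3[neg] <- -b3[neg]
  }
  if (!is.null(Ale) && nrow(Ale) > 0) {
    bl <- ble - as.numeric(Ale %*% lb2)
    pos <- bl >= 0
    A1 <- rbind(A1, Ale[pos, , drop = FALSE])
    b1 <- c(b1, bl[pos])
    A2 <- -Ale[!pos, , drop = FALSE]
    b2 <- -bl[!pos]
  } else {
    A2 <- NULL; b2 <- NULL
  }
  res <- boot::simplex(a = obj, A1 = A1, b1 = b1,
                       A2 = A2, b2 = b2, A3 = A3, b3 = b3,
                       maxi = FALSE, n.iter = 50 * (n + nrow(A1)))
  if (res$solved != 1) return(NULL)
  x <- as.numeric(res$soln) + lb2
  list(x = x, objective = sum(obj * x), status = "optimal")
}

#' Solve a continuity (MOMA-style) quadratic step
#'
#' Minimises `sum((x[idx] - ref)^2)` subject to the same constraint system as
#' [solve_lp()], with a tiny ridge on the remaining variables so the Hessian
#' stays positive definite.
#'
#' @param idx indices of the variables pulled toward `ref`.
#' @param ref reference values (previous-step fluxes).
#' @inheritParams solve_lp
#' @keywords internal
solve_moma_qp <- function(idx, ref, n, Aeq = NULL, beq = NULL,
                          Ale = NULL, ble = NULL, lb = NULL, ub = NULL,
                          ridge = 1e-8) {
  D <- diag(ridge, n)
  diag(D)[idx] <- 2
  d <- rep(0, n)
  d[idx] <- 2 * ref
  x <- try(solve_qp_raw(D, d, Aeq, beq, Ale, ble, lb, ub), silent = TRUE)
  if (inherits(x, "try-error")) {
    return(list(x = rep(NA_real_, n), status = "infeasible"))
  }
  list(x = x, penalty = sum((x[idx] - ref)^2), status = "optimal")
}
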