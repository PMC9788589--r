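# Internal convex-optimization core.
#
# Everything the pipeline solves is expressed over the polyhedron
#   P = { v : S v = 0, lb <= v <= ub }  (optionally with extra equalities)
# and handled by quadprog::solve.QP (dual active-set, deterministic):
#   * min-norm feasibility / witness fluxes:  min ||v||^2 over P
#   * FBA LPs: exact Tikhonov regularization, min eps/2 ||v||^2 - f'v with
#     eps driven down until the achieved objective f'v stabilizes; for small
#     enough eps the minimizer is exactly the least-norm maximizer of f'v
#     over P (exact regularization), so the path also yields the l2-minimal
#     LP optimum.
#   * Euclidean projections onto P or onto the flux cone (SPOT).
# Tolerances live in fluxgem_tol().

#' Numerical tolerances used across the pipeline
#'
#' @return named list: `feasibility` (constraint residuals, 1e-6),
#'   `uniqueness` (agreement between equivalent solves, 1e-5),
#'   `convergence` (solver objective stabilization, 1e-9).
#' @export
fluxgem_tol <- function() {
  list(feasibility = 1e-6, uniqueness = 1e-5, convergence = 1e-9)
}

# min 1/2 v'v - d'v  s.t.  Aeq v = beq, lb <= v <= ub
# returns list(v, status) with status "optimal" or "infeasible"
qp_box <- function(d, Aeq, beq, lb, ub) {
  n <- length(d)
  stopifnot(length(lb) == n, length(ub) == n)
  if (!is.null(Aeq)) {
    # solve.QP needs linearly independent equality rows; drop dependent ones
    # (QR with pivoting) and verify them against the solution afterwards
    qrA <- qr(t(Aeq))
    keep <- sort(qrA$pivot[seq_len(qrA$rank)])
    dropped <- setdiff(seq_len(nrow(Aeq)), keep)
    Aeq_drop <- Aeq[dropped, , drop = FALSE]; beq_drop <- beq[dropped]
    Aeq <- Aeq[keep, , drop = FALSE]; beq <- beq[keep]
  }
  fin_lb <- is.finite(lb); fin_ub <- is.finite(ub)
  Amat <- cbind(if (!is.null(Aeq)) t(Aeq) else NULL,
                diag(n)[, fin_lb, drop = FALSE],
                -diag(n)[, fin_ub, drop = FALSE])
  bvec <- c(if (!is.null(Aeq)) beq else numeric(0), lb[fin_lb], -ub[fin_ub])
  meq <- if (is.null(Aeq)) 0L else length(beq)
  res <- tryCatch(
    quadprog::solve.QP(Dmat = diag(n), dvec = d, Amat = Amat, bvec = bvec, meq = meq),
    error = function(e) e)
  if (inherits(res, "error")) {
    return(list(v = rep(NA_real_, n), status = "infeasible",
                message = conditionMessage(res)))
  }
  v <- res$solution
  if (!is.null(Aeq) && length(beq_drop) > 0) {
    resid <- abs(as.numeric(Aeq_drop %*% v) - beq_drop)
    if (any(resid > fluxgem_tol()$feasibility)) {
      return(list(v = rep(NA_real_, n), status = "infeasible",
                  message = "inconsistent dependent equality constraints"))
    }
  }
  list(v = v, status = "optimal", message = "")
}

# Least-norm point of P (with optional extra equalities): min ||v||^2.
# Used for task-feasibility witnesses.
min_norm_point <- function(S, lb, ub, Aeq_extra = NULL, beq_extra = NULL) {
  Aeq <- S; beq <- rep(0, nrow(S))
  if (!is.null(Aeq_extra)) { Aeq <- rbind(Aeq, Aeq_extra); beq <- c(beq, beq_extra) }
  qp_box(rep(0, ncol(S)), Aeq, beq, lb, ub)
}

# LP  max f'v over P, solved by the exact-regularization path.
# Returns list(v, z_star, status): v is the l2-minimal maximizer.
solve_fba_lp <- function(S, f, lb, ub) {
  n <- length(f)
  tol <- fluxgem_tol()
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("FBA requires finite bounds (unbounded LP not supported)", call. = FALSE)
  }
  z_prev <- NULL; v_prev <- NULL
  for (t in 10^(2:9)) {
    sol <- qp_box(t * f, S, rep(0, nrow(S)), lb, ub)
    if (sol$status != "optimal") {
      return(list(v = sol$v, z_star = NA_real_, status = "infeasible",
                  message = sol$message))
    }
    z <- sum(f * sol$v)
    if (!is.null(z_prev) &&
        abs(z - z_prev) <= tol$convergence * max(1, abs(z)) &&
        max(abs(sol$v - v_prev)) <= tol$uniqueness) {
      return(list(v = sol$v, z_star = z, status = "optimal", message = ""))
    }
    z_prev <- z; v_prev <- sol$v
  }
  list(v = v_prev, z_star = z_prev, status = "optimal",
       message = "regularization path reached its largest multiplier")
}

# Projection of g onto the cone { w : S_split w = 0, w >= 0 }  (SPOT core):
# min ||w - g||^2  s.t.  S w = 0, w >= 0.
project_flux_cone <- function(S, g) {
  n <- ncol(S)
  sol <- qp_box(g, S, rep(0, nrow(S)), rep(0, n), rep(Inf, n))
  if (sol$status != "optimal") stop("flux-cone projection failed: ", sol$message,
                                    call. = FALSE)
  w <- sol$v
  w[w < 0] <- 0  # clip active-set roundoff
  w
}
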