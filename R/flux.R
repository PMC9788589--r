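#' SPOT objective: flux direction maximally aligned with expression
#'
#' Constructs the objective direction `f'` as the feasible flux pattern
#' with the largest uncentered cosine to the reaction expression scores:
#' `max v.g / (||v|| ||g||)` over steady-state fluxes. Reversible
#' reactions are split into non-negative forward/backward components (each
#' carrying the reaction's score); no-GPR reactions carry weight 0. The
#' ratio objective is scale-invariant, so it is solved as `max g.w` over
#' the cone `{S w = 0, w >= 0}` intersected with the unit ball, which
#' reduces to a Euclidean projection of `g` onto the cone: the optimum is
#' the normalized projection, and the achieved cosine is
#' `||proj(g)|| / ||g||`.
#'
#' The prose description of this construction speaks of Pearson
#' correlation; the printed formula is the uncentered cosine, which is
#' what is implemented (a mean-centered variant is available via
#' `centered = TRUE`, without any claim about equivalence).
#'
#' @param context a `context_model` (or a `metabolic_model` used as-is).
#' @param parent parent model when `context` is a `context_model`.
#' @param scores a `reaction_scores`; no-GPR reactions get weight 0.
#' @param centered use mean-centered scores in the objective (off by
#'   default; the printed formula is uncentered).
#' @return object of class `spot_objective`: `f_prime` (named, unit l2
#'   norm unless degenerate), `achieved_cosine`, `degenerate` flag,
#'   `split_map` (data.frame of reversible reactions and their split
#'   column indices).
#' @export
spot_objective <- function(context, scores, parent = NULL, centered = FALSE) {
  model <- if (inherits(context, "context_model")) {
    context_submodel(context, parent)
  } else context
  rx <- model$reactions
  g <- stats::setNames(rep(0, nrow(rx)), rx$id)
  common <- intersect(rx$id, names(scores$scores))
  g[common] <- scores$scores[common]
  if (centered) g <- pmax(g - mean(g), 0)

  S <- stoich_matrix(model)
  rev <- rx$reversible
  # split space: forward columns for all reactions, backward for reversible
  S_split <- cbind(S, -S[, rev, drop = FALSE])
  g_split <- c(g, g[rev])
  if (sqrt(sum(g_split^2)) < 1e-12) {
    return(structure(list(
      f_prime = stats::setNames(rep(0, nrow(rx)), rx$id),
      achieved_cosine = 0, degenerate = TRUE,
      split_map = data.frame(reaction = rx$id[rev],
                             backward_col = nrow(rx) + seq_len(sum(rev)))),
      class = "spot_objective"))
  }
  w <- project_flux_cone(S_split, g_split)
  norm_w <- sqrt(sum(w^2))
  if (norm_w < 1e-10) {
    return(structure(list(
      f_prime = stats::setNames(rep(0, nrow(rx)), rx$id),
      achieved_cosine = 0, degenerate = TRUE,
      split_map = data.frame(reaction = rx$id[rev],
                             backward_col = nrow(rx) + seq_len(sum(rev)))),
      class = "spot_objective"))
  }
  cosine <- norm_w / sqrt(sum(g_split^2))
  # map back: net flux = forward - backward, then renormalize to unit norm
  net <- w[seq_len(nrow(rx))]
  net[rev] <- net[rev] - w[nrow(rx) + seq_len(sum(rev))]
  f_prime <- net / sqrt(sum(net^2))
  structure(list(f_prime = stats::setNames(f_prime, rx$id),
                 achieved_cosine = cosine, degenerate = FALSE,
                 split_map = data.frame(reaction = rx$id[rev],
                                        backward_col = nrow(rx) + seq_len(sum(rev)))),
            class = "spot_objective")
}

#' Split-space cosine between a flux pattern and reaction scores
#'
#' Computes the alignment metric that [spot_objective()] maximizes, for an
#' arbitrary flux vector: the uncentered cosine in the split space where
#' reversible reactions contribute their score to both directions,
#' `cos = v.g / (||v|| ||g_split||)`. Useful for checking candidate flux
#' patterns against the achieved SPOT optimum.
#'
#' @param model the (context sub)model the pattern lives on.
#' @param scores a `reaction_scores`.
#' @param v named flux vector over the model's reactions.
#' @return numeric scalar.
#' @export
spot_cosine <- function(model, scores, v) {
  rx <- model$reactions
  g <- stats::setNames(rep(0, nrow(rx)), rx$id)
  common <- intersect(rx$id, names(scores$scores))
  g[common] <- scores$scores[common]
  g_split_norm <- sqrt(sum(g^2) + sum(g[rx$reversible]^2))
  vv <- stats::setNames(rep(0, nrow(rx)), rx$id)
  vv[intersect(rx$id, names(v))] <- v[intersect(rx$id, names(v))]
  if (g_split_norm == 0 || all(vv == 0)) return(0)
  sum(abs(vv) * g) / sqrt(sum(vv^2)) / g_split_norm
}

#' Expression-derived flux bounds (E-Flux style)
#'
#' A reaction with GPR score `g_j` is bounded to `[0, g_j]` if
#' irreversible and `[-g_j, g_j]` if reversible; rule-less reactions keep
#' their parent bounds (no expression evidence either way). Exchange
#' reactions carry no GPR rule in practice, so boundary fluxes are not
#' enzyme-limited.
#'
#' @param context a `context_model` or `metabolic_model`.
#' @param scores a `reaction_scores`.
#' @param parent parent model when `context` is a `context_model`.
#' @return data.frame: `reaction`, `lower`, `upper`.
#' @export
eflux2_bounds <- function(context, scores, parent = NULL) {
  model <- if (inherits(context, "context_model")) {
    context_submodel(context, parent)
  } else context
  rx <- model$reactions
  lower <- rx$lower_bound
  upper <- rx$upper_bound
  for (i in seq_len(nrow(rx))) {
    gj <- scores$scores[rx$id[i]]
    if (is.na(gj)) next  # no GPR: parent bounds
    if (rx$reversible[i]) { lower[i] <- -gj; upper[i] <- gj }
    else { lower[i] <- 0; upper[i] <- gj }
  }
  data.frame(reaction = rx$id, lower = lower, upper = upper,
             stringsAsFactors = FALSE)
}

#' E-Flux2 flux prediction: FBA then l2-norm minimization
#'
#' Stage 1 maximizes `f'.v` subject to steady state (`S v = 0`) and the
#' expression-derived bounds, giving the FBA optimum `z*`. Stage 2
#' minimizes the Euclidean norm `sum(v_j^2)` over the optimal face
#' (`f'.v = z*` within 1e-6 slack), whose strictly convex objective makes
#' the returned flux unique.
#'
#' @param context a `context_model` or `metabolic_model`.
#' @param f_prime named objective vector from [spot_objective()] (its
#'   `f_prime` element), or any objective over the model's reactions.
#' @param bounds data.frame from [eflux2_bounds()] (reaction, lower,
#'   upper); defaults to the model bounds when `NULL`.
#' @param parent parent model when `context` is a `context_model`.
#' @return object of class `flux_result`: `state`, `v` (named flux,
#'   mmol/gDW/h), `z_star`, `residual` (`||S v||_inf`), `l2_norm`,
#'   `solver_status`.
#' @export
eflux2_solve <- function(context, f_prime, bounds = NULL, parent = NULL,
                         state = NA_character_) {
  model <- if (inherits(context, "context_model")) {
    context_submodel(context, parent)
  } else context
  rx <- model$reactions
  S <- stoich_matrix(model)
  if (is.null(bounds)) {
    lb <- rx$lower_bound; ub <- rx$upper_bound
  } else {
    sel <- match(rx$id, bounds$reaction)
    if (any(is.na(sel))) stop("bounds do not cover all reactions", call. = FALSE)
    lb <- bounds$lower[sel]; ub <- bounds$upper[sel]
  }
  f <- rep(0, nrow(rx))
  common <- intersect(rx$id, names(f_prime))
  f[match(common, rx$id)] <- f_prime[common]

  stage1 <- solve_fba_lp(S, f, lb, ub)
  if (stage1$status != "optimal") {
    stop("FBA stage infeasible: ", stage1$message, call. = FALSE)
  }
  z_star <- stage1$z_star
  # stage 2: min ||v||^2 on the optimal face f'v = z*
  stage2 <- qp_box(rep(0, length(f)), rbind(S, f), c(rep(0, nrow(S)), z_star),
                   lb, ub)
  v <- if (stage2$status == "optimal") stage2$v else stage1$v
  v <- stats::setNames(v, rx$id)
  structure(list(state = state, v = v, z_star = z_star,
                 residual = max(abs(S %*% v)),
                 l2_norm = sqrt(sum(v^2)),
                 solver_status = "optimal"),
            class = "flux_result")
}

#' Filter predicted fluxes to the measurable set
#'
#' A reaction is measurable if its flux magnitude exceeds the threshold
#' (default 0.1 mmol/gDW/h, strict) in at least one state; measurable
#' reactions are retained across all states' columns.
#'
#' @param results list of `flux_result` (one per state).
#' @param threshold magnitude threshold, strict inequality. Default 0.1.
#' @return reactions x states numeric matrix of signed fluxes (union of
#'   reactions over states; a reaction absent from a state's context
#'   carries 0 there). Empty matrix with a warning when nothing passes.
#' @export
measurable_fluxes <- function(results, threshold = 0.1) {
  stopifnot(length(results) >= 1L)
  states <- vapply(results, function(r) r$state, character(1))
  all_rx <- unique(unlist(lapply(results, function(r) names(r$v))))
  mat <- matrix(0, nrow = length(all_rx), ncol = length(results),
                dimnames = list(all_rx, states))
  for (j in seq_along(results)) {
    mat[names(results[[j]]$v), j] <- results[[j]]$v
  }
  keep <- apply(abs(mat) > threshold, 1, any)
  if (!any(keep)) {
    warning("no reaction exceeds the measurable-flux threshold", call. = FALSE)
  }
  mat[keep, , drop = FALSE]
}
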