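#' Read a metabolic task list from JSON
#'
#' Format: `[{"id", "description", "inputs":[{"metabolite","max"}],
#' "outputs":[{"metabolite","min"}]}]`. A task asks: can the network
#' produce each output at its stated minimum rate, given uptake of each
#' input up to its stated maximum, at steady state?
#'
#' @param path JSON file path.
#' @return list of `metabolic_task` objects.
#' @export
read_tasks <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(t) {
    metabolic_task(id = t$id,
                   inputs = lapply(t$inputs, function(x)
                     list(metabolite = x$metabolite, max = as.numeric(x$max))),
                   outputs = lapply(t$outputs, function(x)
                     list(metabolite = x$metabolite, min = as.numeric(x$min))),
                   description = if (is.null(t$description)) "" else t$description)
  })
}

#' Construct a metabolic task
#'
#' @param id task identifier.
#' @param inputs list of `list(metabolite=, max=)` uptake allowances.
#' @param outputs list of `list(metabolite=, min=)` production demands; at
#'   least one minimum must be positive.
#' @param description free text.
#' @return object of class `metabolic_task`.
#' @export
metabolic_task <- function(id, inputs, outputs, description = "") {
  mins <- vapply(outputs, function(x) x$min, numeric(1))
  if (!any(mins > 0)) stop("task ", id, " demands no positive output", call. = FALSE)
  structure(list(id = id, inputs = inputs, outputs = outputs,
                 description = description),
            class = "metabolic_task")
}

#' Serialize a task list to JSON
#' @param tasks list of `metabolic_task`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tasks <- function(tasks, path) {
  out <- lapply(tasks, function(t) {
    list(id = t$id, description = t$description,
         inputs = lapply(t$inputs, function(x)
           list(metabolite = x$metabolite, max = x$max)),
         outputs = lapply(t$outputs, function(x)
           list(metabolite = x$metabolite, min = x$min)))
  })
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             path)
  invisible(path)
}

# Extended steady-state system for a task: the model's S plus one temporary
# uptake column (+1, 0 <= v <= max) per input and one temporary demand
# column (-1, 0 <= v <= min) per output. Feasibility is decided by
# maximizing total demand flux: the task passes iff every demand column can
# reach its cap simultaneously (shortfall ~ 0). This LP is always feasible
# (v = 0), so infeasibility of the task shows up as a positive shortfall —
# which also serves as the greedy gap-fill score.
task_lp <- function(model, task, reaction_ids = NULL) {
  mets_needed <- c(vapply(task$inputs, function(x) x$metabolite, character(1)),
                   vapply(task$outputs, function(x) x$metabolite, character(1)))
  unknown <- setdiff(mets_needed, model$metabolites$id)
  if (length(unknown)) stop("task ", task$id, " references unknown metabolites: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  # restriction to a reaction subset keeps the full metabolite space (rows
  # with no surviving reaction are trivially balanced), so task metabolites
  # only need to exist in the parent
  if (is.null(reaction_ids)) reaction_ids <- model$reactions$id
  sel <- match(reaction_ids, model$reactions$id)
  S <- stoich_matrix(model, reaction_ids)
  lb <- model$reactions$lower_bound[sel]
  ub <- model$reactions$upper_bound[sel]
  n0 <- ncol(S)
  for (inp in task$inputs) {
    col <- rep(0, nrow(S)); col[match(inp$metabolite, rownames(S))] <- 1
    S <- cbind(S, col); lb <- c(lb, 0); ub <- c(ub, inp$max)
  }
  demand_idx <- integer(0)
  for (outp in task$outputs) {
    col <- rep(0, nrow(S)); col[match(outp$metabolite, rownames(S))] <- -1
    S <- cbind(S, col); lb <- c(lb, 0); ub <- c(ub, outp$min)
    demand_idx <- c(demand_idx, ncol(S))
  }
  f <- rep(0, ncol(S)); f[demand_idx] <- 1
  sol <- solve_fba_lp(S, f, lb, ub)
  required <- sum(vapply(task$outputs, function(x) x$min, numeric(1)))
  shortfall <- max(0, required - sol$z_star)
  list(sol = sol, shortfall = shortfall, n0 = n0, S = S)
}

#' Check whether a model can perform a metabolic task
#'
#' Builds the steady-state LP with temporary uptake reactions for the
#' task's inputs (bounded by the stated maxima) and temporary demand
#' reactions for its outputs (required at the stated minima), and decides
#' feasibility at tolerance 1e-6 on the demand shortfall and constraint
#' residuals, returning a witness flux when feasible.
#'
#' @param model a `metabolic_model`, or a `context_model` together with
#'   `parent`.
#' @param task a `metabolic_task`; its metabolites must exist in the model.
#' @param parent parent model, required when `model` is a `context_model`.
#' @return list: `feasible` (logical), `witness` (named flux vector over
#'   the model's reactions when feasible, else `NULL`), `shortfall`
#'   (unmet demand, 0 when feasible), `residual` (steady-state residual).
#' @export
check_task <- function(model, task, parent = NULL) {
  reaction_ids <- NULL
  if (inherits(model, "context_model")) {
    if (is.null(parent)) stop("checking a context_model requires its parent",
                              call. = FALSE)
    if (model$parent_id != parent$id) {
      stop("context was extracted from parent ", model$parent_id,
           ", not ", parent$id, call. = FALSE)
    }
    reaction_ids <- model$kept_reactions
    model <- parent
  }
  lp <- task_lp(model, task, reaction_ids)
  if (is.null(reaction_ids)) reaction_ids <- model$reactions$id
  tol <- fluxgem_tol()$feasibility
  resid <- max(abs(lp$S %*% lp$sol$v))
  feasible <- lp$shortfall <= tol && resid <= tol
  witness <- stats::setNames(lp$sol$v[seq_len(lp$n0)], reaction_ids)
  list(feasible = feasible, witness = if (feasible) witness else NULL,
       shortfall = lp$shortfall, residual = resid)
}

#' Gap-fill a context model until every metabolic task passes
#'
#' For each failing task, searches the reactions excluded at extraction
#' time for a minimal-cardinality rescue set: an exhaustive size-ordered
#' subset search (smallest sets first, within a fixed probe budget) when
#' the candidate pool has at most `exact_cutoff` reactions, otherwise
#' (or past the budget) a greedy fallback (repeatedly add
#' the single excluded reaction that most reduces the task's demand
#' shortfall), flagged in the result. Ties between equal-cardinality sets
#' are broken lexicographically on reaction ids. Added reactions are
#' tagged `task_rescued` in the provenance.
#'
#' @param context a `context_model`.
#' @param parent its parent `metabolic_model`; every task must be feasible
#'   on the parent (else error).
#' @param tasks list of `metabolic_task`.
#' @param exact_cutoff largest candidate-pool size for the exhaustive
#'   search (default 20).
#' @return the rescued `context_model`, with attribute `"gap_fill_method"`
#'   (named per task: `"none"`, `"exact"` or `"greedy"`).
#' @export
gap_fill <- function(context, parent, tasks, exact_cutoff = 20L) {
  methods <- character(0)
  for (task in tasks) {
    if (!check_task(parent, task)$feasible) {
      stop("task ", task$id, " is infeasible even on the parent model",
           call. = FALSE)
    }
    if (check_task(context, task, parent)$feasible) {
      methods[task$id] <- "none"
      next
    }
    candidates <- sort(setdiff(parent$reactions$id, context$kept_reactions))
    found <- NULL
    budget <- 20000  # total subsets the exhaustive search may probe
    if (length(candidates) <= exact_cutoff) {
      methods[task$id] <- "exact"
      probed <- 0
      for (k in seq_along(candidates)) {
        if (probed + choose(length(candidates), k) > budget) break
        probed <- probed + choose(length(candidates), k)
        # combn over a sorted vector enumerates subsets of each size in
        # lexicographic order, so the first feasible one wins the tie-break
        combos <- utils::combn(candidates, k, simplify = FALSE)
        for (subset in combos) {
          if (check_task(add_rescued(context, subset), task, parent)$feasible) {
            found <- subset
            break
          }
        }
        if (!is.null(found)) break
      }
    }
    if (is.null(found)) {
      methods[task$id] <- "greedy"
      current <- context
      added <- character(0)
      repeat {
        pool <- sort(setdiff(parent$reactions$id, current$kept_reactions))
        if (length(pool) == 0L || length(added) > 10L) break
        shortfalls <- vapply(pool, function(r) {
          check_task(add_rescued(current, r), task, parent)$shortfall
        }, numeric(1))
        pick <- pool[which.min(shortfalls)]
        added <- c(added, pick)
        current <- add_rescued(current, pick)
        if (check_task(current, task, parent)$feasible) { found <- added; break }
      }
    }
    if (is.null(found)) {
      stop("gap_fill could not rescue task ", task$id, call. = FALSE)
    }
    context <- add_rescued(context, found)
  }
  attr(context, "gap_fill_method") <- methods
  context
}

add_rescued <- function(context, reaction_ids) {
  new <- setdiff(reaction_ids, context$kept_reactions)
  context$kept_reactions <- c(context$kept_reactions, new)
  context$provenance[new] <- "task_rescued"
  context
}
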