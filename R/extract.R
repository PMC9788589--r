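#' Extract a context-specific model by the TPM threshold rule
#'
#' Keeps every reaction whose GPR score is strictly greater than the
#' threshold (default 1 TPM), tagged `expression_supported`; reactions
#' without a GPR rule are retained by default, tagged `no_gpr_retained`
#' (exclusion in the source procedure happens only through gene rules);
#' everything else is dropped. Task rescue is a separate step
#' ([gap_fill()]).
#'
#' @param model the parent `metabolic_model`.
#' @param scores a `reaction_scores` for one state covering the model.
#' @param threshold TPM threshold; strict inequality. Default 1.
#' @param keep_no_gpr retain rule-less reactions (default `TRUE`).
#' @return object of class `context_model`: `parent_id`, `state`,
#'   `kept_reactions`, `provenance` (named character over kept reactions,
#'   one tag each), `threshold`.
#' @export
threshold_extract <- function(model, scores, threshold = 1.0, keep_no_gpr = TRUE) {
  covered <- c(names(scores$scores), scores$no_gpr)
  missing <- setdiff(model$reactions$id, covered)
  if (length(missing)) stop("scores do not cover reactions: ",
                            paste(utils::head(missing, 5), collapse = ", "),
                            call. = FALSE)
  supported <- names(scores$scores)[scores$scores > threshold]
  kept <- supported
  prov <- stats::setNames(rep("expression_supported", length(supported)), supported)
  if (keep_no_gpr) {
    no_gpr <- intersect(model$reactions$id, scores$no_gpr)
    kept <- c(kept, no_gpr)
    prov[no_gpr] <- "no_gpr_retained"
  }
  kept <- intersect(model$reactions$id, kept)  # parent order
  structure(list(parent_id = model$id, state = scores$state,
                 kept_reactions = kept, provenance = prov[kept],
                 threshold = threshold),
            class = "context_model")
}

#' @export
print.context_model <- function(x, ...) {
  tab <- table(x$provenance)
  cat(sprintf("<context_model> state %s (parent %s): %d reactions kept [%s]\n",
              x$state, x$parent_id, length(x$kept_reactions),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Materialize a context model as a standalone metabolic model
#'
#' @param context a `context_model`.
#' @param parent its parent `metabolic_model`.
#' @return a `metabolic_model` restricted to the kept reactions.
#' @export
context_submodel <- function(context, parent) {
  if (context$parent_id != parent$id) {
    stop("context was extracted from parent ", context$parent_id,
         ", not ", parent$id, call. = FALSE)
  }
  subset_model(parent, context$kept_reactions,
               id = paste0(parent$id, "_", context$state))
}
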