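#' Construct and validate a constraint-based metabolic model
#'
#' The container for a genome-scale metabolic model (GEM): reactions with
#' stoichiometry, flux bounds (mmol/gDW/h), one subsystem label each and an
#' optional GPR rule; metabolites with compartments; a gene list. Transport
#' and exchange flags are always derived from stoichiometry, never trusted
#' from input: a reaction is *exchange* if it touches a single metabolite
#' (a boundary source/sink) and *transport* if it moves some chemical
#' species between two compartments. Reversibility is derived as
#' `lower_bound < 0`.
#'
#' @param id model identifier.
#' @param compartments data.frame with columns `id`, `name`.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `subsystem`, `gpr`.
#' @param stoichiometry named list (one entry per reaction id) of named
#'   numeric vectors: negative coefficients are consumed, positive produced.
#' @param genes character vector of gene identifiers.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, compartments, metabolites, reactions,
                            stoichiometry, genes) {
  reactions$lower_bound <- as.numeric(reactions$lower_bound)
  reactions$upper_bound <- as.numeric(reactions$upper_bound)
  reactions$gpr <- ifelse(is.na(reactions$gpr), "", as.character(reactions$gpr))
  model <- structure(
    list(id = id,
         compartments = as.data.frame(compartments, stringsAsFactors = FALSE),
         metabolites = as.data.frame(metabolites, stringsAsFactors = FALSE),
         reactions = as.data.frame(reactions, stringsAsFactors = FALSE),
         stoichiometry = stoichiometry[as.character(reactions$id)],
         genes = as.character(genes)),
    class = "metabolic_model")
  model <- derive_reaction_flags(model)
  validate_model(model)
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d reactions, %d metabolites, %d genes, %d compartments\n",
              x$id, nrow(x$reactions), nrow(x$metabolites), length(x$genes),
              nrow(x$compartments)))
  invisible(x)
}

# chemical species identity of a metabolite: its name when given, else the id
# with the trailing _<compartment> stripped
metabolite_species <- function(model) {
  sp <- model$metabolites$name
  ids <- model$metabolites$id
  comp <- model$metabolites$compartment
  fallback <- mapply(function(i, cp) sub(paste0("_", cp, "$"), "", i), ids, comp)
  out <- ifelse(is.na(sp) | !nzchar(sp), fallback, sp)
  stats::setNames(out, ids)
}

derive_reaction_flags <- function(model) {
  species <- metabolite_species(model)
  comp <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
  n <- nrow(model$reactions)
  is_tr <- logical(n); is_ex <- logical(n)
  for (i in seq_len(n)) {
    st <- model$stoichiometry[[i]]
    st <- st[st != 0]
    mets <- names(st)
    is_ex[i] <- length(mets) == 1L
    if (length(mets) >= 2L) {
      sp <- species[mets]
      cp <- comp[mets]
      for (s in unique(sp)) {
        sel <- sp == s
        if (length(unique(cp[sel])) >= 2L) { is_tr[i] <- TRUE; break }
      }
    }
  }
  model$reactions$reversible <- model$reactions$lower_bound < 0
  model$reactions$is_transport <- is_tr
  model$reactions$is_exchange <- is_ex
  model
}

#' Validate a metabolic model's structural invariants
#'
#' Checks identifier uniqueness, dangling metabolite/gene references, bound
#' ordering, compartment references and subsystem labels; stops with an
#' error naming the offending identifiers on the first violation.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly.
#' @export
validate_model <- function(model) {
  rx <- model$reactions
  dup <- rx$id[duplicated(rx$id)]
  if (length(dup)) stop("duplicate reaction ids: ", paste(unique(dup), collapse = ", "),
                        call. = FALSE)
  dup <- model$metabolites$id[duplicated(model$metabolites$id)]
  if (length(dup)) stop("duplicate metabolite ids: ", paste(unique(dup), collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(model$metabolites$compartment, model$compartments$id)
  if (length(bad)) stop("undeclared compartments: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  all_mets <- unique(unlist(lapply(model$stoichiometry, names)))
  bad <- setdiff(all_mets, model$metabolites$id)
  if (length(bad)) stop("reactions reference undeclared metabolites: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (any(is.na(rx$subsystem) | !nzchar(rx$subsystem))) {
    stop("reactions without a subsystem label: ",
         paste(rx$id[is.na(rx$subsystem) | !nzchar(rx$subsystem)], collapse = ", "),
         call. = FALSE)
  }
  bad <- rx$id[rx$lower_bound > rx$upper_bound]
  if (length(bad)) stop("lower_bound > upper_bound for reactions: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  gpr_gene_list <- unique(unlist(lapply(rx$gpr, function(g) gpr_genes(parse_gpr(g)))))
  bad <- setdiff(gpr_gene_list, model$genes)
  if (length(bad)) stop("GPR rules reference undeclared genes: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  invisible(model)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids optional subset (and ordering) of reaction columns.
#' @return dense numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoich_matrix <- function(model, reaction_ids = NULL) {
  if (is.null(reaction_ids)) reaction_ids <- model$reactions$id
  mets <- model$metabolites$id
  S <- matrix(0, nrow = length(mets), ncol = length(reaction_ids),
              dimnames = list(mets, reaction_ids))
  for (j in seq_along(reaction_ids)) {
    st <- model$stoichiometry[[reaction_ids[j]]]
    S[names(st), j] <- st
  }
  S
}

#' Subset a model to a reaction set
#'
#' Keeps the given reactions plus the metabolites, genes and compartments
#' they reference. Used to materialize context-specific models.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids reactions to keep.
#' @param id id of the resulting model.
#' @return a `metabolic_model`.
#' @export
subset_model <- function(model, reaction_ids, id = paste0(model$id, "_subset")) {
  reaction_ids <- reaction_ids[reaction_ids %in% model$reactions$id]
  rx <- model$reactions[match(reaction_ids, model$reactions$id), , drop = FALSE]
  st <- model$stoichiometry[rx$id]
  mets_used <- unique(unlist(lapply(st, names)))
  mets <- model$metabolites[model$metabolites$id %in% mets_used, , drop = FALSE]
  comps <- model$compartments[model$compartments$id %in% mets$compartment, , drop = FALSE]
  genes <- unique(unlist(lapply(rx$gpr, function(g) gpr_genes(parse_gpr(g)))))
  metabolic_model(id, comps, mets, rx[, c("id", "name", "lower_bound",
                                          "upper_bound", "subsystem", "gpr")],
                  st, genes)
}

#' Read a metabolic model from its JSON dialect
#'
#' The dialect: top level `{"id", "compartments":[{"id","name"}],
#' "metabolites":[{"id","name","compartment"}], "reactions":[{"id","name",
#' "stoichiometry":{met_id: coef}, "lower_bound","upper_bound","subsystem",
#' "gpr"}], "genes":[id]}`. Coefficients: negative = consumed, positive =
#' produced. Units mmol/gDW/h throughout.
#'
#' @param path path to a JSON model file.
#' @return a validated `metabolic_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed model JSON in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  for (field in c("id", "compartments", "metabolites", "reactions", "genes")) {
    if (is.null(raw[[field]])) stop("model JSON missing field: ", field, call. = FALSE)
  }
  grab <- function(lst, field, default = NA_character_) {
    vapply(lst, function(x) {
      v <- x[[field]]
      if (is.null(v)) default else as.character(v)
    }, character(1))
  }
  comps <- data.frame(id = grab(raw$compartments, "id"),
                      name = grab(raw$compartments, "name"),
                      stringsAsFactors = FALSE)
  mets <- data.frame(id = grab(raw$metabolites, "id"),
                     name = grab(raw$metabolites, "name", ""),
                     compartment = grab(raw$metabolites, "compartment"),
                     stringsAsFactors = FALSE)
  rx <- data.frame(id = grab(raw$reactions, "id"),
                   name = grab(raw$reactions, "name", ""),
                   lower_bound = as.numeric(grab(raw$reactions, "lower_bound")),
                   upper_bound = as.numeric(grab(raw$reactions, "upper_bound")),
                   subsystem = grab(raw$reactions, "subsystem"),
                   gpr = grab(raw$reactions, "gpr", ""),
                   stringsAsFactors = FALSE)
  st <- lapply(raw$reactions, function(x) {
    coefs <- unlist(x$stoichiometry)
    if (is.null(coefs)) stop("reaction ", x$id, " has no stoichiometry", call. = FALSE)
    stats::setNames(as.numeric(coefs), names(coefs))
  })
  names(st) <- rx$id
  metabolic_model(as.character(raw$id), comps, mets, rx, st,
                  unlist(raw$genes, use.names = FALSE))
}

#' Write a metabolic model to its JSON dialect
#'
#' The output is canonical: fixed field order, metabolites/reactions in
#' their stored order, stoichiometry keys sorted. `read_model()` then
#' `write_model()` round-trips byte-identically.
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  rx_list <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    st <- model$stoichiometry[[r$id]]
    st <- st[order(names(st), method = "radix")]
    list(id = r$id, name = r$name,
         stoichiometry = as.list(st),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         subsystem = r$subsystem, gpr = r$gpr)
  })
  met_list <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    list(id = m$id, name = m$name, compartment = m$compartment)
  })
  comp_list <- lapply(seq_len(nrow(model$compartments)), function(i) {
    cm <- model$compartments[i, ]
    list(id = cm$id, name = cm$name)
  })
  out <- list(id = model$id, compartments = comp_list, metabolites = met_list,
              reactions = rx_list, genes = as.list(model$genes))
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
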