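#' Constraint-based metabolic model
#'
#' A `metabolic_model` bundles a metabolite table, a reaction table and the
#' sparse stoichiometric matrix S (rows = metabolites, columns = reactions).
#' Fluxes follow COBRA conventions: mmol/gDW/h, exchange reactions written as
#' `met ->` so that negative flux is uptake and positive flux is secretion.
#'
#' @param metabolites tibble with columns `id`, `name`, `compartment`.
#' @param reactions tibble with columns `id`, `lower_bound`, `upper_bound`,
#'   `enzyme_associated` (logical) and optionally `name`,
#'   `objective_coefficient`.
#' @param stoichiometry named list: for each reaction id, a named numeric
#'   vector of metabolite coefficients (negative = consumed).
#' @param objective_id id of the objective (biomass) reaction, or `NULL` to
#'   take the reaction with a non-zero `objective_coefficient`.
#' @param big_bound finite stand-in for "arbitrarily large" bounds.
#' @param require_objective error when no objective reaction can be
#'   determined (disable for reduced/auxiliary networks).
#'
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            objective_id = NULL, big_bound = 1000,
                            require_objective = TRUE) {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"enzyme_associated" %in% names(reactions)) {
    reactions$enzyme_associated <- FALSE
  }
  if (!"objective_coefficient" %in% names(reactions)) {
    reactions$objective_coefficient <- 0
  }

  reactions$lower_bound <- pmax(reactions$lower_bound, -big_bound)
  reactions$upper_bound <- pmin(reactions$upper_bound, big_bound)
  reactions$reversible <- reactions$lower_bound < 0 & reactions$upper_bound > 0

  stoichiometry <- stoichiometry[reactions$id]
  S <- stoich_to_matrix(stoichiometry, metabolites$id, reactions$id)
  reactions$is_exchange <- Matrix::colSums(S != 0) == 1

  if (is.null(objective_id)) {
    hit <- reactions$id[reactions$objective_coefficient != 0]
    if (length(hit) >= 1) objective_id <- hit[[1]]
  }

  model <- structure(
    list(metabolites = metabolites, reactions = reactions, S = S,
         objective_id = objective_id, big_bound = big_bound),
    class = "metabolic_model"
  )
  validate_model(model, require_objective = require_objective)
}

stoich_to_matrix <- function(stoichiometry, met_ids, rxn_ids) {
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(rxn_ids)) {
    st <- stoichiometry[[rxn_ids[[k]]]]
    st <- st[st != 0]
    if (length(st) == 0) next
    idx <- match(names(st), met_ids)
    if (anyNA(idx)) {
      abort(paste0("Reaction '", rxn_ids[[k]], "' references unknown metabolite(s): ",
                   paste(names(st)[is.na(idx)], collapse = ", ")))
    }
    i <- c(i, idx); j <- c(j, rep(k, length(st))); x <- c(x, unname(st))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, bound ordering (naming the offending reaction),
#' non-empty compartments and objective presence.
#'
#' @param model a `metabolic_model`.
#' @param require_objective error when no objective reaction is set.
#' @return the model, invisibly usable in pipes.
#' @export
validate_model <- function(model, require_objective = TRUE) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) abort("Duplicate metabolite ids.")
  if (anyDuplicated(rxns$id)) abort("Duplicate reaction ids.")
  if (any(!nzchar(mets$compartment))) abort("Empty metabolite compartment tag.")
  bad <- rxns$id[rxns$lower_bound > rxns$upper_bound]
  if (length(bad) > 0) {
    abort(paste0("lower_bound > upper_bound for reaction(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (require_objective &&
      (is.null(model$objective_id) || !model$objective_id %in% rxns$id)) {
    abort("Model has no objective reaction (set objective_id or an objective_coefficient).")
  }
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions (",
      sum(x$reactions$is_exchange), " exchanges)\n", sep = "")
  cat("objective: ", x$objective_id %||% "<none>", "\n", sep = "")
  invisible(x)
}

# named stoichiometry vector of one reaction (name-safe for 1-row matrices)
reaction_stoich <- function(model, rxn_id) {
  named_column(model$S, rxn_id)
}

named_column <- function(S, j) {
  col <- S[, j, drop = FALSE]
  v <- as.numeric(col)
  names(v) <- rownames(col)
  v[v != 0]
}

# stoichiometry matrix as list keyed by reaction id
stoich_as_list <- function(model) {
  lapply(setNames(model$reactions$id, model$reactions$id),
         function(r) reaction_stoich(model, r))
}

#' Apply a growth-medium specification to exchange bounds
#'
#' The medium is a tibble with columns `exchange_id`, `uptake_bound`
#' (maximum uptake rate, encoded as lower bound `-uptake_bound`) and
#' `secretion_allowed` (0/1; 0 sets the release bound to zero).
#'
#' @param model a `metabolic_model` (or cost-augmented model).
#' @param medium medium tibble, or `NULL` for no change.
#' @return the model with adjusted exchange bounds.
#' @export
apply_medium <- function(model, medium) {
  if (is.null(medium)) return(model)
  medium <- as_tibble(medium)
  missing <- setdiff(medium$exchange_id, model$reactions$id)
  if (length(missing) > 0) {
    warn(paste0("Medium references absent exchange(s): ",
                paste(missing, collapse = ", ")))
  }
  for (k in seq_len(nrow(medium))) {
    id <- medium$exchange_id[[k]]
    i <- match(id, model$reactions$id)
    if (is.na(i)) next
    model$reactions$lower_bound[[i]] <- -abs(medium$uptake_bound[[k]])
    if (!is.null(medium$secretion_allowed) && medium$secretion_allowed[[k]] == 0) {
      model$reactions$upper_bound[[i]] <- 0
    }
  }
  model$reactions$reversible <-
    model$reactions$lower_bound < 0 & model$reactions$upper_bound > 0
  model
}
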