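# Protein-cost model: per-direction cost coefficients and the cost-augmented
# model (reversible enzyme reactions split into forward/backward parts, cost
# accumulated on a pseudo-metabolite drained by a single sink reaction).

COST_METABOLITE_ID <- "protein_cost__x"
COST_SINK_ID <- "COST_SINK"

#' Thermodynamic penalty factor for one reaction direction
#'
#' The penalty `exp(alpha_scaled * dG0)` applies only to reversible reactions
#' and is reciprocal between directions: the thermodynamically favorable
#' direction (negative dG0) gets a factor below one, the unfavorable one a
#' factor above one. With the default `alpha_scaled = 0.02` per kcal/mol the
#' exponent is `0.02 * dG0[kcal/mol]`, independent of temperature (the scaling
#' constant is defined as 0.02 RT mol/kcal, cancelling the RT denominator of
#' the Boltzmann form).
#'
#' @param dG0 standard Gibbs free energy of reaction, kcal/mol.
#' @param direction `"forward"` or `"backward"`.
#' @param reversible logical; irreversible reactions get factor 1.
#' @param alpha_scaled exponent scale per kcal/mol (default 0.02).
#' @return positive penalty factor (vectorized over `dG0`).
#' @export
#' @examples
#' thermo_factor(0, "forward", TRUE)            # 1
#' thermo_factor(50, "forward", TRUE)           # exp(1)
#' thermo_factor(5, "forward", TRUE) * thermo_factor(5, "backward", TRUE)  # 1
thermo_factor <- function(dG0, direction = c("forward", "backward"),
                          reversible = TRUE, alpha_scaled = 0.02) {
  direction <- match.arg(direction)
  if (any(!is.finite(dG0))) abort("thermo_factor(): non-finite dG0.")
  sgn <- if (direction == "forward") 1 else -1
  ifelse(reversible, exp(sgn * alpha_scaled * dG0), 1)
}

#' Impute missing enzyme molecular weights by the median
#'
#' Every entry flagged for imputation receives the median of the known
#' (non-imputed) enzyme molecular weights; an even count uses the arithmetic
#' mean of the two central values.
#'
#' @param costs a `cost_table`.
#' @return the cost table with `mw_kda` filled and `mw_imputed = TRUE` on
#'   imputed rows.
#' @export
impute_missing_weights <- function(costs) {
  pending <- costs$enzyme_associated & is.na(costs$mw_kda)
  if (!any(pending)) return(costs)
  known <- costs$mw_kda[costs$enzyme_associated & !is.na(costs$mw_kda)]
  if (length(known) == 0) {
    abort("Cannot impute molecular weights: no known enzyme MW in the table.")
  }
  costs$mw_kda[pending] <- median(known)
  costs$mw_imputed <- costs$enzyme_associated & (costs$mw_imputed | pending)
  costs
}

#' Per-direction protein cost coefficients
#'
#' Builds the cost each usable reaction direction adds per unit flux, under
#' one of four cost types: `"mw"` (molecular weight alone), `"thermo"`
#' (thermodynamic penalty alone), `"combined"` (MW x penalty) or `"uniform"`
#' (1 per enzyme-associated direction, i.e. minimization of total enzymatic
#' flux). Non-enzymatic reactions always cost zero. The cost-table enzyme flag
#' overrides the model's gene-association flag; reactions absent from both are
#' treated as non-enzymatic.
#'
#' @param model a [metabolic_model()].
#' @param costs a `cost_table` (imputed via [impute_missing_weights()] if
#'   needed).
#' @param cost_type one of `"combined"`, `"mw"`, `"thermo"`, `"uniform"`.
#' @param alpha_scaled thermodynamic exponent scale (see [thermo_factor()]).
#' @return a `cost_coefficients` tibble: `reaction_id`, `enzyme_associated`,
#'   `cost_forward`, `cost_backward` (`NA` for irreversible), `cost_type`.
#' @export
build_cost_coefficients <- function(model, costs,
                                    cost_type = c("combined", "mw", "thermo", "uniform"),
                                    alpha_scaled = 0.02) {
  cost_type <- match.arg(cost_type)
  costs <- impute_missing_weights(costs)

  rxns <- model$reactions
  idx <- match(rxns$id, costs$reaction_id)
  # the cost-table flag overrides the model's gene association; reactions the
  # table does not list fall back to the model flag
  enz <- ifelse(!is.na(idx), costs$enzyme_associated[idx],
                rxns$enzyme_associated)

  mw_at <- function(i) if (is.na(i)) NA_real_ else costs$mw_kda[[i]]
  missing <- rxns$id[enz & is.na(vapply(idx, mw_at, numeric(1)))]
  if (length(missing) > 0) {
    abort(paste0("Enzyme reaction(s) missing from the cost table after ",
                 "imputation: ", paste(missing, collapse = ", ")))
  }

  mw <- ifelse(enz, costs$mw_kda[idx], 0)
  dG0 <- ifelse(enz, costs$dG0_kcal_mol[idx], 0)
  rev <- rxns$reversible

  base_f <- switch(cost_type,
    uniform = as.numeric(enz),
    mw = mw,
    thermo = thermo_factor(dG0, "forward", rev, alpha_scaled),
    combined = mw * thermo_factor(dG0, "forward", rev, alpha_scaled)
  )
  base_b <- switch(cost_type,
    uniform = as.numeric(enz),
    mw = mw,
    thermo = thermo_factor(dG0, "backward", rev, alpha_scaled),
    combined = mw * thermo_factor(dG0, "backward", rev, alpha_scaled)
  )
  out <- tibble(
    reaction_id = rxns$id,
    enzyme_associated = enz,
    cost_forward = ifelse(enz, base_f, 0),
    cost_backward = dplyr::case_when(
      !rxns$lower_bound < 0 ~ NA_real_,
      enz ~ base_b,
      TRUE ~ 0
    ),
    cost_type = cost_type
  )
  class(out) <- c("cost_coefficients", class(out))
  out
}

#' Build the cost-augmented model
#'
#' Every enzyme-associated reaction that can run backwards (`lower_bound < 0`)
#' is replaced by two irreversible parts `<id>__f` / `<id>__b` with negated
#' stoichiometries on the real metabolites; each enzyme-associated direction
#' additionally produces the cost pseudo-metabolite at its per-direction cost
#' coefficient. A single sink reaction consumes the cost metabolite, so the
#' sink flux at steady state equals the total protein cost. Non-enzymatic
#' reactions are left untouched.
#'
#' @param model a [metabolic_model()].
#' @param coeffs `cost_coefficients` from [build_cost_coefficients()].
#' @return a `cost_augmented_model`: list with the augmented `model`, the
#'   `original` model, the `split_map` tibble and the cost metabolite/sink ids.
#' @export
augment_model <- function(model, coeffs) {
  stopifnot(identical(coeffs$reaction_id, model$reactions$id))
  rxns <- model$reactions
  clash <- intersect(
    c(paste0(rxns$id, "__f"), paste0(rxns$id, "__b"),
      COST_METABOLITE_ID, COST_SINK_ID),
    c(rxns$id, model$metabolites$id))
  if (length(clash) > 0) {
    abort(paste0("Generated id(s) collide with existing ids: ",
                 paste(clash, collapse = ", ")))
  }

  mets <- dplyr::bind_rows(model$metabolites,
    tibble(id = COST_METABOLITE_ID, name = "protein cost carrier",
           compartment = "cost"))

  ids <- character(0); lbs <- numeric(0); ubs <- numeric(0)
  enz <- logical(0); obj <- numeric(0); stoich <- list()
  split_from <- character(0); split_fwd <- character(0); split_bwd <- character(0)

  for (k in seq_len(nrow(rxns))) {
    id <- rxns$id[[k]]
    st <- reaction_stoich(model, id)
    is_enz <- coeffs$enzyme_associated[[k]]
    cf <- coeffs$cost_forward[[k]]
    cb <- coeffs$cost_backward[[k]]
    if (is_enz && rxns$lower_bound[[k]] < 0) {
      fid <- paste0(id, "__f"); bid <- paste0(id, "__b")
      st_f <- st; st_b <- -st
      if (cf > 0) st_f[COST_METABOLITE_ID] <- cf
      if (!is.na(cb) && cb > 0) st_b[COST_METABOLITE_ID] <- cb
      ids <- c(ids, fid, bid)
      lbs <- c(lbs, 0, 0)
      ubs <- c(ubs, max(rxns$upper_bound[[k]], 0), -rxns$lower_bound[[k]])
      enz <- c(enz, TRUE, TRUE)
      obj <- c(obj, 0, 0)
      stoich[[fid]] <- st_f; stoich[[bid]] <- st_b
      split_from <- c(split_from, id)
      split_fwd <- c(split_fwd, fid); split_bwd <- c(split_bwd, bid)
    } else {
      if (is_enz && cf > 0) st[COST_METABOLITE_ID] <- cf
      ids <- c(ids, id)
      lbs <- c(lbs, rxns$lower_bound[[k]]); ubs <- c(ubs, rxns$upper_bound[[k]])
      enz <- c(enz, is_enz)
      obj <- c(obj, rxns$objective_coefficient[[k]])
      stoich[[id]] <- st
      split_from <- c(split_from, id)
      split_fwd <- c(split_fwd, id); split_bwd <- c(split_bwd, NA_character_)
    }
  }

  # sink bound: production is capped by sum over directions of |coef| * bound
  cap <- 0
  for (id in ids) {
    cc <- stoich[[id]][COST_METABOLITE_ID]
    if (!is.na(cc)) cap <- cap + abs(cc) * max(abs(lbs[ids == id]), abs(ubs[ids == id]))
  }
  sink_ub <- max(cap, model$big_bound)
  ids <- c(ids, COST_SINK_ID)
  lbs <- c(lbs, 0); ubs <- c(ubs, sink_ub)
  enz <- c(enz, FALSE); obj <- c(obj, 0)
  stoich[[COST_SINK_ID]] <- setNames(-1, COST_METABOLITE_ID)

  aug_rxns <- tibble(id = ids, name = ids, lower_bound = lbs, upper_bound = ubs,
                     enzyme_associated = enz, objective_coefficient = obj)
  if (!is.null(model$objective_id) && !model$objective_id %in% ids) {
    abort("Objective reaction was split; mark the objective as non-enzymatic or irreversible.")
  }
  aug <- metabolic_model(mets, aug_rxns, stoich,
                         objective_id = model$objective_id,
                         big_bound = max(model$big_bound, sink_ub))

  structure(list(
    model = aug,
    original = model,
    split_map = tibble(reaction_id = unique(split_from),
                       forward_id = split_fwd[!duplicated(split_from)],
                       backward_id = split_bwd[!duplicated(split_from)]),
    coefficients = coeffs,
    cost_metabolite_id = COST_METABOLITE_ID,
    cost_sink_id = COST_SINK_ID
  ), class = "cost_augmented_model")
}

#' @export
print.cost_augmented_model <- function(x, ...) {
  n_split <- sum(!is.na(x$split_map$backward_id))
  cat("<cost_augmented_model> ", nrow(x$model$reactions), " columns (",
      n_split, " reactions split), cost type: ",
      x$coefficients$cost_type[[1]], "\n", sep = "")
  invisible(x)
}

# Recombine augmented fluxes to net fluxes on the original reactions.
net_fluxes_from_split <- function(aug, v_aug) {
  v <- setNames(v_aug, aug$model$reactions$id)
  sm <- aug$split_map
  fwd <- v[sm$forward_id]
  bwd <- ifelse(is.na(sm$backward_id), 0, v[sm$backward_id])
  tibble(reaction_id = sm$reaction_id, flux = unname(fwd - bwd))
}
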