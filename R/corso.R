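# Two-step sub-optimal optimization: maximize the objective, fix it at a
# fraction of the optimum by an equality constraint, then minimize the
# cost-sink flux (and, for reproducibility, lexicographically minimize the
# total split flux at the cost optimum).

aug_lp_parts <- function(aug, medium) {
  m <- apply_medium(aug$model, medium)
  list(S = as.matrix(m$S),
       lb = m$reactions$lower_bound,
       ub = m$reactions$upper_bound,
       ids = m$reactions$id)
}

#' Maximize the objective reaction of a cost-augmented model
#'
#' Plain FBA on the augmented network: maximize the objective flux subject to
#' steady state and bounds under the given medium.
#'
#' @param aug a `cost_augmented_model` from [augment_model()].
#' @param medium medium tibble (see [apply_medium()]) or `NULL`.
#' @return list with `optimum`, `fluxes` (named, augmented columns) and
#'   `status` (`"optimal"`, `"infeasible"`, `"maxiter"`).
#' @export
maximize_objective <- function(aug, medium = NULL) {
  parts <- aug_lp_parts(aug, medium)
  obj <- as.numeric(parts$ids == aug$model$objective_id)
  res <- lp_solve(obj, parts$S, parts$lb, parts$ub, maximize = TRUE)
  if (res$status != "optimal") {
    return(list(optimum = NA_real_, fluxes = NULL, status = res$status))
  }
  list(optimum = res$objective,
       fluxes = setNames(res$fluxes, parts$ids),
       status = "optimal")
}

#' Cost-minimal flux distribution at a fixed objective fraction
#'
#' Fixes the objective flux at `fraction` times its maximum (equality, via
#' coincident bounds) and minimizes the cost-sink flux. Ties among alternate
#' cost-minimal optima are broken by a secondary minimization of the total
#' flux through the split (forward/backward) columns at the fixed cost
#' optimum, which also removes futile forward+backward cycles. Fluxes below
#' 1e-9 in magnitude are snapped to zero.
#'
#' @param aug a `cost_augmented_model`.
#' @param medium medium tibble or `NULL`.
#' @param fraction objective fraction in (0, 1].
#' @param optimum optionally, a precomputed objective optimum (skips the
#'   first LP).
#' @param geq_objective use a `>=` bound instead of the equality constraint.
#' @return a `corso_solution`: `fraction`, `objective_value`, `net_fluxes`
#'   tibble, `split_fluxes` (named vector), `total_cost`, `status`.
#' @export
solve_corso <- function(aug, medium = NULL, fraction = 1,
                        optimum = NULL, geq_objective = FALSE) {
  if (!(fraction > 0 && fraction <= 1)) abort("fraction must lie in (0, 1].")
  if (is.null(optimum)) {
    fba <- maximize_objective(aug, medium)
    if (fba$status != "optimal") {
      return(corso_solution(aug, fraction, NA_real_, NULL, fba$status))
    }
    optimum <- fba$optimum
  }
  target <- fraction * optimum

  parts <- aug_lp_parts(aug, medium)
  iobj <- match(aug$model$objective_id, parts$ids)
  isink <- match(aug$cost_sink_id, parts$ids)
  lb <- parts$lb; ub <- parts$ub
  lb[iobj] <- target
  if (!geq_objective) ub[iobj] <- target

  cost_obj <- as.numeric(parts$ids == aug$cost_sink_id)
  res <- lp_solve(cost_obj, parts$S, lb, ub, maximize = FALSE)
  if (res$status != "optimal") {
    return(corso_solution(aug, fraction, target, NULL, res$status))
  }
  total_cost <- res$objective

  # lexicographic cleanup: fix the cost, minimize total split flux
  split_cols <- with(aug$split_map, c(forward_id[!is.na(backward_id)],
                                      backward_id[!is.na(backward_id)]))
  v <- res$fluxes
  if (length(split_cols) > 0) {
    lb2 <- lb; ub2 <- ub
    lb2[isink] <- total_cost
    ub2[isink] <- total_cost
    tie_obj <- as.numeric(parts$ids %in% split_cols)
    res2 <- lp_solve(tie_obj, parts$S, lb2, ub2, maximize = FALSE)
    if (res2$status == "optimal") v <- res2$fluxes
  }
  v[near_zero(v)] <- 0
  corso_solution(aug, fraction, target, setNames(v, parts$ids), "optimal",
                 total_cost = total_cost)
}

corso_solution <- function(aug, fraction, objective_value, split_fluxes,
                           status, total_cost = NA_real_) {
  net <- if (is.null(split_fluxes)) NULL else net_fluxes_from_split(aug, split_fluxes)
  structure(list(
    fraction = fraction,
    objective_value = objective_value,
    net_fluxes = net,
    split_fluxes = split_fluxes,
    total_cost = if (is.null(split_fluxes)) total_cost else
      unname(split_fluxes[aug$cost_sink_id]),
    enzyme_associated = setNames(aug$coefficients$enzyme_associated,
                                 aug$coefficients$reaction_id),
    status = status
  ), class = "corso_solution")
}

#' @export
print.corso_solution <- function(x, ...) {
  cat("<corso_solution> fraction ", format(x$fraction), ", status ", x$status,
      "\n", sep = "")
  if (x$status == "optimal") {
    cat("objective ", format(x$objective_value), ", total cost ",
        format(x$total_cost), "\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.corso_solution <- function(x, ...) {
  if (is.null(x$net_fluxes)) {
    return(tibble(reaction_id = character(0), flux = numeric(0),
                  enzyme_associated = logical(0)))
  }
  dplyr::mutate(x$net_fluxes,
                enzyme_associated = unname(x$enzyme_associated[.data$reaction_id]))
}

#' @exportS3Method generics::glance
glance.corso_solution <- function(x, ...) {
  tibble(fraction = x$fraction, objective_value = x$objective_value,
         total_cost = x$total_cost, status = x$status,
         n_active = if (is.null(x$net_fluxes)) NA_integer_ else
           sum(x$net_fluxes$flux != 0))
}

#' Sweep the objective fraction and collect cost-minimal solutions
#'
#' One [solve_corso()] per fraction (ascending); the FBA optimum is computed
#' once. Per-fraction failures are reported in the `status` column and do not
#' stop the sweep. Minimal cost is non-decreasing in the fraction because the
#' feasible regions are nested.
#'
#' @param aug a `cost_augmented_model`.
#' @param medium medium tibble or `NULL`.
#' @param fractions numeric vector in (0, 1]; default 0.50 to 1.00 in steps
#'   of 0.01.
#' @return a `corso_sweep` tibble: `fraction`, `status`, `objective_value`,
#'   `total_cost`, and the full solution objects in the `solution`
#'   list-column.
#' @export
sweep_corso <- function(aug, medium = NULL, fractions = seq(0.5, 1, by = 0.01)) {
  if (any(fractions <= 0 | fractions > 1)) abort("fractions must lie in (0, 1].")
  fractions <- sort(fractions)
  fba <- maximize_objective(aug, medium)
  if (fba$status != "optimal") {
    abort(paste0("FBA step failed: ", fba$status))
  }
  sols <- purrr::map(fractions, function(f) {
    solve_corso(aug, medium, fraction = f, optimum = fba$optimum)
  })
  n_bad <- sum(purrr::map_chr(sols, "status") != "optimal")
  if (n_bad > 0) {
    warn(paste0(n_bad, " of ", length(sols), " sweep fractions did not solve."))
  }
  out <- tibble(
    fraction = fractions,
    status = purrr::map_chr(sols, "status"),
    objective_value = purrr::map_dbl(sols, "objective_value"),
    total_cost = purrr::map_dbl(sols, "total_cost"),
    solution = sols
  )
  class(out) <- c("corso_sweep", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.corso_sweep <- function(x, ...) {
  ok <- x$status == "optimal"
  purrr::map_dfr(x$solution[ok], function(sol) {
    dplyr::mutate(tidy(sol), fraction = sol$fraction, .before = 1)
  })
}

#' @exportS3Method generics::glance
glance.corso_sweep <- function(x, ...) {
  tibble(n_fractions = nrow(x), n_optimal = sum(x$status == "optimal"),
         min_cost = suppressWarnings(min(x$total_cost, na.rm = TRUE)),
         max_cost = suppressWarnings(max(x$total_cost, na.rm = TRUE)))
}

#' Normalize a solution's net fluxes
#'
#' Divides every net flux either by the glucose -> glucose-6-phosphate flux
#' (`"glc_g6p"`) or by the total absolute flux through enzyme-associated
#' reactions (`"total_enzyme_flux"`).
#'
#' @param sol a `corso_solution`.
#' @param mode `"glc_g6p"` or `"total_enzyme_flux"`.
#' @param glc_g6p_id reaction id of the glucose phosphorylation step
#'   (required for `"glc_g6p"`).
#' @return tibble `reaction_id`, `flux`, `normalized`.
#' @export
normalize_fluxes <- function(sol, mode = c("glc_g6p", "total_enzyme_flux"),
                             glc_g6p_id = NULL) {
  mode <- match.arg(mode)
  if (is.null(sol$net_fluxes)) abort("Solution has no fluxes (not optimal).")
  fl <- sol$net_fluxes
  denom <- if (mode == "glc_g6p") {
    if (is.null(glc_g6p_id)) abort("glc_g6p mode requires glc_g6p_id.")
    i <- match(glc_g6p_id, fl$reaction_id)
    if (is.na(i)) abort(paste0("Unknown reaction id: ", glc_g6p_id))
    abs(fl$flux[[i]])
  } else {
    enz <- sol$enzyme_associated[fl$reaction_id]
    sum(abs(fl$flux[enz]))
  }
  if (denom <= 0) abort("Normalization denominator is zero.")
  dplyr::mutate(fl, normalized = .data$flux / denom)
}
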