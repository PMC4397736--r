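# Comparison of simulated against experimentally measured flux distributions
# (metabolic flux analysis tables): Pearson correlation and sum of squared
# error over the shared reaction set, optionally across a whole sweep.

#' Pair simulated and experimental fluxes by reaction id
#'
#' MFA networks name reactions differently from reconstructions, so an
#' optional id map (columns `sim_id`, `exp_id`, optionally `sign`) translates
#' and sign-corrects before pairing. Reversible reactions measured as net
#' fluxes are compared on the simulated NET flux.
#'
#' @param sim tibble with `reaction_id` and a flux column (`flux` or
#'   `normalized`), or a named numeric vector.
#' @param exp same format for the experimental fluxes.
#' @param id_map optional tibble `sim_id`, `exp_id`, `sign`.
#' @param value which simulated column to use when `sim` is a tibble.
#' @return tibble `reaction_id`, `sim`, `exp` for the shared ids; unmatched
#'   ids are attached as attributes `unmatched_sim` / `unmatched_exp`.
#' @export
align_flux_vectors <- function(sim, exp, id_map = NULL, value = "flux") {
  as_map <- function(x, value) {
    if (is.numeric(x) && !is.null(names(x))) return(x)
    x <- as_tibble(x)
    col <- if (value %in% names(x)) value else "flux"
    setNames(x[[col]], x$reaction_id)
  }
  sim <- as_map(sim, value)
  exp <- as_map(exp, value = "flux")

  if (!is.null(id_map)) {
    id_map <- as_tibble(id_map)
    sgn <- if ("sign" %in% names(id_map)) id_map$sign else rep(1, nrow(id_map))
    keep <- id_map$sim_id %in% names(sim)
    translated <- setNames(sim[id_map$sim_id[keep]] * sgn[keep],
                           id_map$exp_id[keep])
    sim <- translated
  }
  shared <- intersect(names(sim), names(exp))
  if (length(shared) < 2) {
    abort(paste0("Only ", length(shared),
                 " shared reaction id(s); need at least 2 to compare."))
  }
  out <- tibble(reaction_id = shared,
                sim = unname(sim[shared]),
                exp = unname(exp[shared]))
  attr(out, "unmatched_sim") <- setdiff(names(sim), shared)
  attr(out, "unmatched_exp") <- setdiff(names(exp), shared)
  out
}

#' Correlation and squared error between paired flux vectors
#'
#' @param pairs tibble from [align_flux_vectors()] (columns `sim`, `exp`).
#' @return one-row tibble `pearson_r`, `sse`, `n_matched`. With zero variance
#'   in either vector `pearson_r` is `NA` (undefined); the SSE is always
#'   computed.
#' @export
compare_fluxes <- function(pairs) {
  if (nrow(pairs) < 2) abort("Need at least 2 pairs to compare.")
  r <- if (stats::sd(pairs$sim) == 0 || stats::sd(pairs$exp) == 0) {
    NA_real_
  } else {
    cor(pairs$sim, pairs$exp, method = "pearson")
  }
  tibble(pearson_r = r,
         sse = sum((pairs$sim - pairs$exp)^2),
         n_matched = nrow(pairs))
}

#' Compare a whole sweep against one experimental flux table
#'
#' @param sweep a `corso_sweep`.
#' @param exp experimental fluxes (tibble `reaction_id`, `flux`).
#' @param id_map optional id translation (see [align_flux_vectors()]).
#' @param normalize normalization applied to each solution before comparison
#'   (`"none"`, `"glc_g6p"`, `"total_enzyme_flux"`).
#' @param glc_g6p_id glucose -> G6P reaction id for `"glc_g6p"`.
#' @return tibble `fraction`, `pearson_r`, `sse`, `n_matched`.
#' @export
compare_sweep <- function(sweep, exp, id_map = NULL, normalize = "none",
                          glc_g6p_id = NULL) {
  ok <- sweep$status == "optimal"
  purrr::map_dfr(sweep$solution[ok], function(sol) {
    fl <- if (normalize == "none") {
      sol$net_fluxes
    } else {
      dplyr::select(
        normalize_fluxes(sol, mode = normalize, glc_g6p_id = glc_g6p_id),
        "reaction_id", flux = "normalized")
    }
    pairs <- align_flux_vectors(fl, exp, id_map = id_map)
    dplyr::mutate(compare_fluxes(pairs), fraction = sol$fraction, .before = 1)
  })
}
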