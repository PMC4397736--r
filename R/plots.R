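# ggplot2 displays for sweeps and pathway decompositions.

#' @exportS3Method ggplot2::autoplot
autoplot.corso_sweep <- function(object, ...) {
  ok <- object[object$status == "optimal", ]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$fraction, y = .data$total_cost)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "objective fraction f",
                  y = "minimal protein cost (cost-sink flux)",
                  title = "Cost of sub-optimal growth") +
    ggplot2::theme_minimal()
}

#' Flux profiles across a sweep
#'
#' Net flux of selected reactions as a function of the objective fraction.
#'
#' @param sweep a `corso_sweep`.
#' @param reactions reaction ids to display (default: the 8 largest-range
#'   fluxes).
#' @return a ggplot object.
#' @export
plot_flux_profiles <- function(sweep, reactions = NULL) {
  long <- tidy(sweep)
  if (is.null(reactions)) {
    rng <- long |>
      dplyr::group_by(.data$reaction_id) |>
      dplyr::summarise(range = diff(range(.data$flux)), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(range))
    reactions <- head(rng$reaction_id, 8)
  }
  long <- long[long$reaction_id %in% reactions, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fraction, y = .data$flux)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~reaction_id, scales = "free_y") +
    ggplot2::labs(x = "objective fraction f", y = "net flux (mmol/gDW/h)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.fundamental_pathways <- function(object, ...) {
  if (!"atp_potential" %in% names(object)) {
    abort("Run atp_potential() / fundamental_pathways() before plotting.")
  }
  df <- tidy(object)
  df <- df[!df$is_internal_loop & is.finite(df$cost_per_atp) &
             df$atp_potential > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$atp_potential,
                                   y = .data$cost_per_atp,
                                   color = .data$classification)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_manual(values = c(OP = "#1f6fb4", NOP = "#d43f3a",
                                           other = "grey55")) +
    ggplot2::labs(x = "ATP potential (mmol ATP / mmol glucose)",
                  y = "protein cost per mmol ATP",
                  color = NULL,
                  title = "Energy pathways: yield versus cost") +
    ggplot2::theme_minimal()
}
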