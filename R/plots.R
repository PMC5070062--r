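#' Bar summary of fixation-duration percentages
#'
#' Group mean FD% per AOI with standard-error bars, faceted by task —
#' the usual way these group contrasts are displayed.
#'
#' @param measures Per-participant measures tibble
#'   (see [participant_measures()]).
#' @param aois Which FD measures to show.
#' @return A ggplot object.
#' @export
plot_fd_summary <- function(measures,
                            aois = c("fd_pct_face", "fd_pct_target",
                                     "fd_pct_non_target")) {
  long <- measures |>
    tidyr::pivot_longer(dplyr::all_of(aois), names_to = "aoi",
                        values_to = "fd_pct") |>
    dplyr::mutate(aoi = sub("^fd_pct_", "", .data$aoi)) |>
    dplyr::filter(is.finite(.data$fd_pct)) |>
    dplyr::group_by(.data$task, .data$group, .data$aoi) |>
    dplyr::summarise(
      mean = mean(.data$fd_pct),
      se = sd(.data$fd_pct) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$aoi, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(0.9), width = 0.25
    ) +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(x = "area of interest", y = "fixation duration (% of on-trial FD)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Effect-size overview of a group-comparison table
#'
#' Partial eta squared per tested variable, faceted by task, with the
#' FDR decision mapped to the point shape and the conventional
#' small/medium/large bands drawn as reference lines.
#'
#' @param object A [compare_groups()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ja_comparisons <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$eta2_partial,
                                       y = .data$variable,
                                       shape = .data$fdr_significant)) +
    ggplot2::geom_vline(xintercept = c(0.01, 0.06, 0.14),
                        linetype = "dotted", colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$task),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16)) +
    ggplot2::labs(x = "partial eta squared", y = NULL,
                  shape = "significant after FDR") +
    ggplot2::theme_minimal()
}
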