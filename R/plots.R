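#' Plot per-end SV frequencies
#'
#' Bar chart of the SV frequency of every chromosome end; ends whose
#' telomere is too short to analyse are drawn as missing.
#'
#' @param stats Per-end stats tibble from [analyze_variation()] /
#'   [tidy.sv_analysis()].
#' @return A ggplot object.
#' @export
plot_sv_frequency <- function(stats) {
  ggplot2::ggplot(stats,
                  ggplot2::aes(x = .data$chrom_id, y = .data$sv_frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~end, ncol = 1) +
    ggplot2::labs(x = "chromosome", y = "SV frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot the positional SV profile along the motif
#'
#' Three bars per motif site (deletion, insertion, base change), both ends
#' shown in the right-end motif coordinate frame.
#'
#' @param profile Profile tibble from [analyze_variation()].
#' @return A ggplot object.
#' @export
plot_sv_profile <- function(profile) {
  long <- tidyr::pivot_longer(profile, c("d_count", "i_count", "c_count"),
                              names_to = "kind", values_to = "count")
  long$kind <- factor(substr(long$kind, 1, 1), levels = c("d", "i", "c"))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$motif_site),
                                     y = .data$count, fill = .data$kind)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::facet_wrap(~end, ncol = 1) +
    ggplot2::labs(x = "motif site (G-rich orientation)", y = "SV count",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_sv_frequency autoplot method: `type = "frequency"` or
#'   `"profile"`.
#' @param object An `sv_analysis`.
#' @param type Which panel to draw.
#' @param ... Unused.
#' @export
autoplot.sv_analysis <- function(object, type = c("frequency", "profile"), ...) {
  type <- match.arg(type)
  if (type == "frequency") plot_sv_frequency(object$stats)
  else plot_sv_profile(object$profile)
}

#' Plot ranked motif candidates
#'
#' Support (chromosome ends) of the top candidate classes.
#'
#' @param object A `motif_report`.
#' @param n_top Number of candidate classes to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motif_report <- function(object, n_top = 10L, ...) {
  cand <- utils::head(object$candidates, n_top)
  ggplot2::ggplot(cand,
                  ggplot2::aes(x = stats::reorder(.data$canonical_motif,
                                                  .data$suppchr_ends),
                               y = .data$suppchr_ends)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "supporting chromosome ends") +
    ggplot2::theme_minimal()
}
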