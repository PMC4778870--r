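#' Plot differential isoform calls
#'
#' Volcano-style view of a screen: isoform fraction difference against the
#' log-odds score, with the two candidate filters drawn as dashed lines and
#' significant events highlighted.
#'
#' @param object An `isoform_calls` tibble from
#'   [call_differential_isoforms()].
#' @param delta_psi_min,log_odds_min Filter thresholds to draw (defaults
#'   match the calling defaults).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot isoform_calls
#' @export
autoplot.isoform_calls <- function(object, delta_psi_min = 0.2,
                                   log_odds_min = 1, ...) {
  df <- tidy(object) |> dplyr::filter(.data$status == "ok")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_psi, y = .data$log_odds,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-delta_psi_min, delta_psi_min),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = log_odds_min, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(Delta * psi ~ "(mutant - control)"),
                  y = expression(log[10] ~ "odds"),
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Plot a mutant/control coverage pair around a breakpoint
#'
#' Per-base pileups of the two genotypes, with the insertion breakpoint
#' marked — the coverage drop-off downstream of a truncating insertion is
#' directly visible.
#'
#' @param mutant,control Coverage profiles (tibbles with `chrom`, `pos`,
#'   `depth`).
#' @param breakpoint Optional 0-based breakpoint coordinate to mark.
#' @return A ggplot object.
#' @export
plot_coverage_pair <- function(mutant, control, breakpoint = NULL) {
  df <- dplyr::bind_rows(mutant = mutant, control = control,
                         .id = "genotype")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "steelblue") +
    ggplot2::facet_wrap(~genotype, ncol = 1) +
    ggplot2::labs(x = "position (0-based)", y = "coverage") +
    ggplot2::theme_minimal()
  if (!is.null(breakpoint)) {
    p <- p + ggplot2::geom_vline(xintercept = breakpoint,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}
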