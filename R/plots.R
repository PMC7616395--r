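#' Plot population dynamics of a run
#'
#' Diploid and tetraploid counts through time, one line per cytotype
#' (diploids red, tetraploids blue). Requires ggplot2.
#'
#' @param trajectory a `ploidy_trajectory`.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(trajectory) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_trajectory() requires the ggplot2 package")
  d <- trajectory$daily
  long <- rbind(
    data.frame(day = d$day, n = d$n_diploid, cytotype = "diploid"),
    data.frame(day = d$day, n = d$n_tetraploid, cytotype = "tetraploid")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$n,
                                     color = .data$cytotype)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = c(diploid = "#c0392b",
                                           tetraploid = "#2e6da4")) +
    ggplot2::labs(x = "day", y = "individuals",
                  title = sprintf("scenario %s, efficiency reduction %g%%",
                                  trajectory$config$scenario,
                                  100 * trajectory$config$reduction)) +
    ggplot2::theme_minimal()
}

#' Plot a metabolic-efficiency sweep
#'
#' Final-window tetraploid proportion against the efficiency reduction,
#' one point per replicate plus the per-reduction mean, faceted by
#' scenario. Requires ggplot2.
#'
#' @param sweep a [sweep_efficiency()] result.
#' @param threshold invasion threshold drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, threshold = 0.95) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_sweep() requires the ggplot2 package")
  means <- stats::aggregate(final_proportion ~ reduction + scenario,
                            data = sweep, FUN = mean)
  ggplot2::ggplot(sweep,
                  ggplot2::aes(x = 100 * .data$reduction,
                               y = .data$final_proportion)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.5, size = 1) +
    ggplot2::geom_point(data = means, shape = 1, size = 3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "tetraploid metabolic-efficiency reduction (%)",
                  y = "final tetraploid proportion") +
    ggplot2::theme_minimal()
}
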