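#' Plot a TSS occupancy profile
#'
#' Line plot of the fraction of TSSs covered per offset bin, as produced by
#' [tss_profile()]. Requires ggplot2.
#'
#' @param profile A [tss_profile()] result.
#' @return A ggplot object.
#' @export
plot_tss_profile <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_tss_profile requires the ggplot2 package")
  }
  profile$mid <- profile$offset + 0.5 * (profile$offset[2] - profile$offset[1])
  ggplot2::ggplot(profile, ggplot2::aes(x = mid, y = fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "distance from TSS (bp)",
                  y = "fraction of TSSs covered") +
    ggplot2::theme_minimal()
}

#' Plot distances to the nearest peak of another set
#'
#' Histogram of [nearest_distance()] values (undefined distances dropped),
#' on a log10(1 + bp) axis so the overlap spike at zero stays visible.
#'
#' @param distances Output of [nearest_distance()].
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_nearest_distance <- function(distances, bins = 50) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_nearest_distance requires the ggplot2 package")
  }
  df <- data.frame(log_dist = log10(1 + distances[!is.na(distances)]))
  ggplot2::ggplot(df, ggplot2::aes(x = log_dist)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::labs(x = "log10(1 + distance to nearest peak, bp)",
                  y = "peaks") +
    ggplot2::theme_minimal()
}
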