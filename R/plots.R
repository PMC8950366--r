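utils::globalVariables(c("time_ns", "value_nm"))

#' Plot a distance or RMSD time series
#'
#' Time on the x axis in ns, value in nm; an optional horizontal line
#' marks the detachment threshold.
#'
#' @param series a \linkS4class{DistanceSeries} or
#'   \linkS4class{RMSDSeries}.
#' @param thresholdNm optional threshold to draw, nm.
#' @return A ggplot object.
#' @export
plotSeries <- function(series, thresholdNm = NULL) {
  df <- data.frame(time_ns = timesPs(series) / 1000,
                   value_nm = valuesNm(series))
  g <- ggplot2::ggplot(df, ggplot2::aes(x = time_ns, y = value_nm)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey25") +
    ggplot2::labs(x = "time (ns)", y = "distance (nm)",
                  title = seriesLabel(series)) +
    ggplot2::theme_minimal()
  if (!is.null(thresholdNm))
    g <- g + ggplot2::geom_hline(yintercept = thresholdNm,
                                 linetype = "dashed", colour = "firebrick")
  g
}
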