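# Base-graphics summary figures: matching-spike latency CDFs by group and
# boxplots of corrected reliability.

#' Plot nearest-spike latency CDFs by group
#'
#' @param latencies named list of latency vectors (seconds), e.g. from
#'   [pooled_latencies()] with `by =`.
#' @param max_window_ms right edge of the window axis (ms, default 25).
#' @param method CDF estimator passed to [latency_cdf()].
#' @param col line colors, recycled over groups.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the matrix of CDF values (grid x group).
#' @export
plot_latency_cdf <- function(latencies, max_window_ms = 25,
                             method = "empirical", col = NULL, ...) {
  stopifnot(is.list(latencies), length(latencies) >= 1L)
  grid_ms <- seq(0, max_window_ms, length.out = 200L)
  cdfs <- vapply(latencies, function(l) {
    latency_cdf(l, grid_ms / 1000, method = method)
  }, numeric(length(grid_ms)))
  if (is.null(col)) col <- seq_len(ncol(cdfs))
  graphics::plot(grid_ms, cdfs[, 1L], type = "l", ylim = c(0, 1), col = col[1L],
                 xlab = "window (ms)", ylab = "cumulative probability", ...)
  if (ncol(cdfs) > 1L) {
    for (k in 2L:ncol(cdfs)) {
      graphics::lines(grid_ms, cdfs[, k],
                      col = col[(k - 1L) %% length(col) + 1L])
    }
  }
  graphics::legend("bottomright", legend = colnames(cdfs), lty = 1,
                   col = col, bty = "n")
  invisible(cdfs)
}

#' Boxplot of corrected reliability by group
#'
#' @param table data.frame as from [reliability_table()].
#' @param grouping grouping column name.
#' @param value value column (default `"corrected"`).
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the boxplot stats.
#' @export
plot_reliability_groups <- function(table, grouping, value = "corrected",
                                    ...) {
  stopifnot(grouping %in% names(table), value %in% names(table))
  f <- stats::as.formula(paste(value, "~", grouping))
  bp <- graphics::boxplot(f, data = table, pch = 3,
                          ylab = "corrected reliability",
                          xlab = grouping, ...)
  invisible(bp)
}
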