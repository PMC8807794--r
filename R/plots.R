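#' Plot estimator errors from the linear-model benchmark
#'
#' Draws mean estimation error (estimate minus analytic log evidence) with
#' +/- 1 SD error bars against model dimension p, one line per estimator —
#' the standard summary figure for comparing TI against the biased AME/HME
#' references.
#'
#' @param benchmark result of [run_linreg_benchmark()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot_benchmark <- function(benchmark, ...) {
  s <- benchmark$summary
  methods <- sort(unique(s$method))
  ps <- sort(unique(s$p))
  em <- sapply(methods, function(m) s$error_mean[s$method == m][order(s$p[s$method == m])])
  sd <- sapply(methods, function(m) s$error_sd[s$method == m][order(s$p[s$method == m])])
  cols <- c(AME = "#1b6ca8", HME = "#c23b22", TI = "black")[methods]
  graphics::matplot(ps, em, type = "b", pch = 16, lty = 1, col = cols,
                    xlab = "number of regression parameters p",
                    ylab = "error in log evidence (nats)", ...)
  for (i in seq_along(methods))
    graphics::arrows(ps, em[, i] - sd[, i], ps, em[, i] + sd[, i],
                     angle = 90, code = 3, length = 0.03, col = cols[i])
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topleft", legend = methods, col = cols, lty = 1,
                   pch = 16, bty = "n")
  invisible(benchmark)
}
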