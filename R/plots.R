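# Simple base-graphics diagnostics.

#' Plot group occupancy time courses
#'
#' Mean z-scored occupancy per outcome against time, thickening
#' FDR-significant stretches.
#'
#' @param x A `timecourse_result`.
#' @param smooth_span Lowess span in seconds (0 disables smoothing).
#' @param rate Sampling rate used for smoothing, default 250.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.timecourse_result <- function(x, smooth_span = 0.2, rate = 250, ...) {
  z <- x$mean_z
  if (smooth_span > 0) {
    z <- t(apply(z, 1, lowess_smooth, rate = rate, span = smooth_span))
  }
  graphics::matplot(x$time, t(z), type = "l", lty = 1,
                    xlab = "time from stimulus (s)",
                    ylab = "occupancy (z)", ...)
  graphics::abline(v = 0, h = 0, col = "grey")
  for (oi in seq_len(nrow(z))) {
    sig <- which(x$significant[oi, ])
    if (length(sig)) {
      graphics::points(x$time[sig], z[oi, sig], pch = 16, cex = 0.4,
                       col = oi)
    }
  }
  graphics::legend("topright", legend = rownames(z), col = seq_len(nrow(z)),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Plot an amplitude-quantile lapse curve set
#'
#' One line per participant (z-scored lapse proportion by amplitude
#' quantile) plus the group mean.
#'
#' @param curves List of `quantile_curve` objects (NULLs dropped).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the participants x quantiles z matrix.
#' @export
plot_quantile_curves <- function(curves, ...) {
  curves <- curves[!vapply(curves, is.null, NA)]
  zmat <- do.call(rbind, lapply(curves, `[[`, "z"))
  k <- ncol(zmat)
  graphics::matplot(seq_len(k), t(zmat), type = "l", lty = 1,
                    col = "grey", xlab = "amplitude quantile",
                    ylab = "lapse proportion (z)", ...)
  graphics::lines(seq_len(k), colMeans(zmat), lwd = 3)
  invisible(zmat)
}
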