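# Base-graphics views of the two curve classes.

#' @export
plot.msd_curve <- function(x, ..., log = "") {
  graphics::plot(x$lag_h, x$msd_um2, log = log,
                 xlab = "lag (h)", ylab = expression(MSD ~ (mu * m^2)),
                 pch = 16, ...)
  invisible(x)
}

#' @export
plot.closure_series <- function(x, ...) {
  graphics::plot(x$t_h, x$closed_pct, type = "l",
                 xlab = "time after barrier removal (h)",
                 ylab = "wound closure (%)", ylim = c(0, 100), ...)
  invisible(x)
}
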