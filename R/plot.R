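## Base-graphics quick-look methods.

#' @export
plot.current_trace <- function(x, ..., max_points = 20000) {
  idx <- if (length(x$time) > max_points) {
    round(seq(1, length(x$time), length.out = max_points))
  } else seq_along(x$time)
  graphics::plot(x$time[idx], x$current[idx], type = "l",
                 xlab = "time (s)", ylab = "current (pA)",
                 main = sprintf("%+g mV", x$holding_potential), ...)
  invisible(x)
}

#' @export
plot.ecs_trace <- function(x, ...) {
  graphics::plot(x$time, x$signal, type = "l", xlab = "time (s)",
                 ylab = "ECS signal (rel.)", ...)
  graphics::abline(v = x$protocol$dark_intervals, lty = 3)
  invisible(x)
}

#' @export
plot.sans_curve <- function(x, ...) {
  graphics::plot(x$q, x$intensity, log = "xy",
                 xlab = expression(q ~ (ring(A)^-1)),
                 ylab = "I(q)", type = "b", pch = 16, cex = 0.5, ...)
  invisible(x)
}

#' @export
plot.cd_spectrum <- function(x, ...) {
  graphics::plot(x$wavelength, x$cd_signal, type = "l",
                 xlab = "wavelength (nm)", ylab = "CD (rel.)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
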