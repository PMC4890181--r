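#' @keywords internal
"_PACKAGE"

## Physical constants
.FARADAY <- 96485.33212   # C mol^-1
.GAS_R <- 8.314462618     # J mol^-1 K^-1

#' Thermal voltage RT/F in millivolts
#'
#' @param temperature_k Absolute temperature in kelvin.
#' @return RT/F in mV (25.693 mV at 298.15 K).
#' @export
rtf_mv <- function(temperature_k = 298.15) {
  stopifnot(is.numeric(temperature_k), temperature_k > 0)
  1000 * .GAS_R * temperature_k / .FARADAY
}

## Evaluate an expression under a fixed RNG seed, restoring the caller's
## RNG state afterwards.  All stochastic generators route through this so a
## single integer seed fixes every output bit-for-bit.
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
  }
  force(expr)
}

## Derive a sub-stream seed (one per trace) from the master seed, kept
## within 32-bit integer range.
substream_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 10007 * k) %% .Machine$integer.max)
}

stop_thylakoidr <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "thylakoidr_error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  }
  invisible(x)
}

## Mean of a signal over a closed time window; errors on empty windows.
window_mean <- function(time, signal, from, to) {
  idx <- time >= from & time <= to
  if (!any(idx)) {
    stop_thylakoidr(
      sprintf("no samples in window [%g, %g] s", from, to),
      "empty_window"
    )
  }
  mean(signal[idx])
}

fmt_num <- function(x) sprintf("%.10g", x)
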