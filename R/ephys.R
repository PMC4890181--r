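## Single-channel analysis: amplitude histograms, unitary-current
## estimation by Gaussian-mixture fitting, half-amplitude idealization,
## branch-wise slope conductance, and Goldman-Hodgkin-Katz selectivity.

#' Build an all-points amplitude histogram of a current trace
#'
#' @param trace A [current_trace()].
#' @param bin_width Bin width in pA (> 0).
#' @return An `amplitude_histogram` with `bin_edges`, `counts` (summing to
#'   the number of samples) and `bin_width`.
#' @export
build_amplitude_histogram <- function(trace, bin_width = 0.1) {
  stopifnot(inherits(trace, "current_trace"))
  if (!length(trace$current)) stop_thylakoidr("empty trace", "empty_trace")
  check_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  lo <- floor(min(trace$current) / bin_width) * bin_width
  hi <- ceiling(max(trace$current) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  counts <- tabulate(findInterval(trace$current, edges,
                                  rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  structure(list(bin_edges = edges, counts = counts, bin_width = bin_width),
            class = "amplitude_histogram")
}

## Weighted K-component Gaussian-mixture EM on binned data
## (bin centers weighted by counts).  Returns means, sds, weights, loglik.
mixture_em <- function(centers, w, mu0, max_iter = 500, tol = 1e-10) {
  k <- length(mu0)
  n <- sum(w)
  mu <- mu0
  sd_all <- sqrt(sum(w * (centers - sum(w * centers) / n)^2) / n)
  sigma <- rep(max(sd_all / k, 1e-6), k)
  pi_k <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) {
      pi_k[j] * stats::dnorm(centers, mu[j], sigma[j])
    }, numeric(length(centers)))
    rowsum_d <- rowSums(dens) + 1e-300
    ll <- sum(w * log(rowsum_d))
    resp <- dens / rowsum_d
    for (j in seq_len(k)) {
      wj <- w * resp[, j]
      nj <- sum(wj)
      pi_k[j] <- nj / n
      if (nj > 0) {
        mu[j] <- sum(wj * centers) / nj
        sigma[j] <- sqrt(sum(wj * (centers - mu[j])^2) / nj)
      }
      sigma[j] <- max(sigma[j], 1e-6)
    }
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, pi = pi_k, loglik = ll, k = k)
}

## Local maxima of smoothed histogram counts, ordered by height.
histogram_modes <- function(hist, min_rel_height = 0.01) {
  counts <- as.numeric(hist$counts)
  sm <- if (length(counts) >= 7) stats::runmed(counts, 5) else counts
  n <- length(sm)
  if (n < 3) return(which.max(sm))
  is_max <- c(FALSE, sm[2:(n - 1)] >= sm[1:(n - 2)] &
                sm[2:(n - 1)] > sm[3:n], FALSE)
  is_max[c(1, n)] <- c(sm[1] > sm[2], sm[n] > sm[n - 1])
  idx <- which(is_max & sm >= min_rel_height * max(sm))
  idx[order(sm[idx], decreasing = TRUE)]
}

#' Estimate the unitary current from an amplitude histogram
#'
#' Fits a Gaussian mixture to the bin centers weighted by counts and
#' returns the separation between the two dominant modes (closed and fully
#' open levels).  The mixture is initialized from the highest peaks of the
#' smoothed histogram; when more than two components are fitted (substates,
#' stacked multi-channel levels), the two with the largest mixing weights
#' are taken as the dominant pair, ties broken towards the larger
#' separation.  A histogram whose binned likelihood prefers a single
#' Gaussian (BIC) carries no resolvable open level and raises a
#' `no_open_events` error.
#'
#' @param hist An `amplitude_histogram` from [build_amplitude_histogram()].
#' @param max_components Maximum number of mixture components (default 2;
#'   raise for traces with substates or stacked openings).
#' @return Unitary current in pA (positive separation), with the fitted
#'   mixture in attribute `"mixture"`.
#' @export
estimate_unitary_current <- function(hist, max_components = 2) {
  stopifnot(inherits(hist, "amplitude_histogram"))
  centers <- (hist$bin_edges[-1] + hist$bin_edges[-length(hist$bin_edges)]) / 2
  w <- as.numeric(hist$counts)
  n <- sum(w)
  modes <- histogram_modes(hist)
  k <- max(2L, min(as.integer(max_components), length(modes)))
  mu0 <- if (length(modes) >= k) centers[modes[seq_len(k)]] else {
    ## fallback init when the smoothed histogram resolves < k peaks
    stats::quantile(rep(centers, times = pmax(round(w / max(w) * 100), 0)),
                    probs = seq(0.1, 0.9, length.out = k), names = FALSE)
  }
  fit_k <- mixture_em(centers, w, sort(mu0))
  mu_bar <- sum(w * centers) / n
  sd_bar <- sqrt(sum(w * (centers - mu_bar)^2) / n)
  ll1 <- sum(w * log(stats::dnorm(centers, mu_bar, max(sd_bar, 1e-6)) + 1e-300))
  bic1 <- -2 * ll1 + 2 * log(n)
  bic_k <- -2 * fit_k$loglik + (3 * fit_k$k - 1) * log(n)
  if (bic1 <= bic_k) {
    stop_thylakoidr("no open events: amplitude histogram is unimodal",
                    "no_open_events")
  }
  ## dominant pair: two largest mixing weights, ties toward larger separation
  ord <- order(fit_k$pi, decreasing = TRUE)
  top <- ord[1:2]
  if (fit_k$k > 2) {
    cand <- ord[fit_k$pi[ord] >= fit_k$pi[ord[2]] - 1e-9]
    if (length(cand) > 2) {
      pairs <- utils::combn(cand, 2)
      seps <- abs(fit_k$mu[pairs[1, ]] - fit_k$mu[pairs[2, ]])
      top <- pairs[, which.max(seps)]
    }
  }
  sep <- abs(diff(fit_k$mu[top]))
  if (sep < hist$bin_width) {
    stop_thylakoidr("no open events: mixture modes are not resolvable",
                    "no_open_events")
  }
  structure(sep, mixture = fit_k)
}

#' Idealize a trace by half-amplitude threshold crossing
#'
#' A sample is open when its absolute current exceeds half the absolute
#' unitary current; an optional substate current adds a third level with
#' thresholds midway between neighbouring levels.  No digital filtering is
#' applied by default; an optional moving-average prefilter is available.
#'
#' @param trace A [current_trace()].
#' @param unitary_current Unitary current in pA (non-zero, signed or not).
#' @param substate_current Optional substate current level in pA.
#' @param prefilter_n Optional odd moving-average length in samples
#'   (default `NULL`, no filtering).
#' @return An `idealization`: data frame `segments` (`level`, `start`,
#'   `duration` in s) tiling the trace, and `open_probability` (open plus
#'   substate time over total time).
#' @export
idealize_half_amplitude <- function(trace, unitary_current,
                                    substate_current = NULL,
                                    prefilter_n = NULL) {
  stopifnot(inherits(trace, "current_trace"))
  if (!is.numeric(unitary_current) || unitary_current == 0) {
    stop_thylakoidr("unitary current must be non-zero", "zero_unitary")
  }
  x <- abs(trace$current)
  if (!is.null(prefilter_n)) {
    stopifnot(prefilter_n >= 1, prefilter_n %% 2 == 1)
    x <- as.numeric(stats::filter(x, rep(1 / prefilter_n, prefilter_n),
                                  sides = 2))
    x[is.na(x)] <- abs(trace$current)[is.na(x)]
  }
  iu <- abs(unitary_current)
  if (is.null(substate_current)) {
    level <- ifelse(x > iu / 2, "open", "closed")
  } else {
    is_ <- abs(substate_current)
    stopifnot(is_ < iu)
    level <- cut(x, c(-Inf, is_ / 2, (is_ + iu) / 2, Inf),
                 labels = c("closed", "substate", "open"))
    level <- as.character(level)
  }
  r <- rle(level)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)]) / trace$sampling_rate
  segments <- data.frame(level = r$values, start = starts,
                         duration = r$lengths / trace$sampling_rate)
  structure(
    list(segments = segments,
         open_probability = mean(level != "closed"),
         per_sample = level),
    class = "idealization"
  )
}

#' Fit branch-wise slope conductance from unitary current-voltage points
#'
#' Least-squares slope through the reversal point, per voltage branch
#' (sign of `V - v_rev`) or as a single branch across all points.  The
#' slope of `i` (pA) against `V - v_rev` (mV) is reported in pS
#' (pA/mV x 1000).
#'
#' @param points Data frame with columns `voltage` (mV) and `current` (pA,
#'   signed unitary current).
#' @param v_rev Reversal potential in mV (default 0, symmetric solutions).
#' @param branches `"split"` for separate positive/negative branches,
#'   `"single"` for one conductance across all voltages.
#' @return A `conductance_fit` with `gamma_pos`, `gamma_neg` (pS, `NA` when
#'   a branch has fewer than two points), `gamma_single`, `v_rev` and
#'   per-branch residuals.
#' @export
fit_branch_conductance <- function(points, v_rev = 0,
                                   branches = c("split", "single")) {
  branches <- match.arg(branches)
  stopifnot(is.data.frame(points),
            all(c("voltage", "current") %in% names(points)))
  dv <- points$voltage - v_rev
  i <- points$current
  slope_ps <- function(sel) {
    if (sum(sel) < 2) return(list(gamma = NA_real_, resid = NULL))
    g <- sum(i[sel] * dv[sel]) / sum(dv[sel]^2)  # pA/mV, through V_rev
    list(gamma = 1000 * g, resid = i[sel] - g * dv[sel])
  }
  if (branches == "single") {
    f <- slope_ps(rep(TRUE, length(dv)))
    if (is.na(f$gamma)) {
      stop_thylakoidr("fewer than 2 points for the conductance fit",
                      "too_few_points")
    }
    fit <- list(gamma_pos = NA_real_, gamma_neg = NA_real_,
                gamma_single = f$gamma, v_rev = v_rev,
                residuals = list(single = f$resid), branches = "single")
  } else {
    fp <- slope_ps(dv > 0)
    fn <- slope_ps(dv < 0)
    if (is.na(fp$gamma) && is.na(fn$gamma)) {
      stop_thylakoidr("fewer than 2 points in both branches",
                      "too_few_points")
    }
    fit <- list(gamma_pos = fp$gamma, gamma_neg = fn$gamma,
                gamma_single = NA_real_, v_rev = v_rev,
                residuals = list(positive = fp$resid, negative = fn$resid),
                branches = "split")
  }
  structure(fit, class = "conductance_fit")
}

#' Goldman-Hodgkin-Katz reversal potential for a K+/Cl- condition
#'
#' Monovalent bi-ionic form with the anion on the opposite side of the
#' concentration fraction:
#' `V_rev = (RT/F) * ln((p_ratio * [K]_trans + [Cl]_cis) /
#'                      (p_ratio * [K]_cis + [Cl]_trans))`,
#' cis relative to trans, with `p_ratio = P_K / P_Cl`.
#'
#' @param p_ratio Permeability ratio P_K/P_Cl (>= 0; 0 gives the Nernst
#'   potential for Cl-).
#' @param ionic An [ionic_condition()] declaring K and Cl on both sides.
#' @return Reversal potential in mV.
#' @examples
#' ghk_reversal_potential(0, ionic_condition(c(K = 300, Cl = 300),
#'                                           c(K = 100, Cl = 100))) # +28.2
#' @export
ghk_reversal_potential <- function(p_ratio, ionic) {
  stopifnot(inherits(ionic, "ionic_condition"))
  check_number(p_ratio, "p_ratio", lower = 0)
  if (!all(c("K", "Cl") %in% names(ionic$cis))) {
    stop("K and Cl concentrations must be set on both sides", call. = FALSE)
  }
  num <- p_ratio * ionic$trans[["K"]] + ionic$cis[["Cl"]]
  den <- p_ratio * ionic$cis[["K"]] + ionic$trans[["Cl"]]
  if (num <= 0 || den <= 0) {
    stop("degenerate concentrations: zero numerator or denominator",
         call. = FALSE)
  }
  rtf_mv(ionic$temperature_k) * log(num / den)
}

#' Invert the GHK voltage equation for the permeability ratio
#'
#' Closed-form inversion of [ghk_reversal_potential()]:
#' with `x = exp(v_rev / (RT/F))`,
#' `p_ratio = ([Cl]_cis - x * [Cl]_trans) / (x * [K]_cis - [K]_trans)`.
#' The round trip with the forward equation is the identity.
#'
#' @param v_rev Measured reversal potential in mV (cis relative to trans).
#' @param ionic An [ionic_condition()]; must be an asymmetric KCl gradient,
#'   otherwise the ratio is unidentifiable.
#' @return A `selectivity_result` with `v_rev` (mV) and `p_ratio`
#'   (P_K/P_Cl; the anion-first convention reports P_Cl:P_K = 1:p_ratio).
#' @export
fit_permeability_ratio <- function(v_rev, ionic) {
  stopifnot(inherits(ionic, "ionic_condition"))
  if (!all(c("K", "Cl") %in% names(ionic$cis))) {
    stop("K and Cl concentrations must be set on both sides", call. = FALSE)
  }
  k_c <- ionic$cis[["K"]]; k_t <- ionic$trans[["K"]]
  cl_c <- ionic$cis[["Cl"]]; cl_t <- ionic$trans[["Cl"]]
  if (abs(k_c - k_t) < 1e-12 && abs(cl_c - cl_t) < 1e-12) {
    stop_thylakoidr(
      "unidentifiable: symmetric ionic condition carries no selectivity information",
      "unidentifiable")
  }
  rtf <- rtf_mv(ionic$temperature_k)
  v_lo <- rtf * log(k_t / k_c)    # p_ratio -> Inf limit (K Nernst)
  v_hi <- rtf * log(cl_c / cl_t)  # p_ratio = 0 limit (Cl Nernst)
  rng <- sort(c(v_lo, v_hi))
  if (v_rev < rng[1] - 1e-9 || v_rev > rng[2] + 1e-9) {
    stop_thylakoidr(
      sprintf("v_rev = %.3g mV outside the attainable range [%.3g, %.3g] mV",
              v_rev, rng[1], rng[2]),
      "vrev_out_of_range")
  }
  x <- exp(v_rev / rtf)
  p <- (cl_c - x * cl_t) / (x * k_c - k_t)
  structure(list(v_rev = v_rev, p_ratio = max(p, 0)),
            class = "selectivity_result")
}

#' GHK current-voltage relation for a K+/Cl- condition
#'
#' Goldman-Hodgkin-Katz current equation summed over K+ (z = +1) and Cl-
#' (z = -1), in relative units (P_Cl = 1, P_K = `p_ratio`); positive
#' current is carried by cations moving cis to trans.  Its zero crossing is
#' the GHK reversal potential, which makes it the reference forward model
#' for selectivity estimation from current-voltage data.
#'
#' @param voltages Holding potentials in mV.
#' @param p_ratio Permeability ratio P_K/P_Cl.
#' @param ionic An [ionic_condition()].
#' @return Numeric vector of currents (relative units).
#' @export
ghk_current <- function(voltages, p_ratio, ionic) {
  stopifnot(inherits(ionic, "ionic_condition"))
  rtf <- rtf_mv(ionic$temperature_k)
  u <- voltages / rtf
  flux <- function(p, z, c_cis, c_trans) {
    zu <- z * u
    ## series expansion near 0 mV where the GHK form is 0/0
    ifelse(abs(zu) < 1e-8,
           p * z * ((c_cis - c_trans) + zu * (c_cis + c_trans) / 2),
           p * z * zu * (c_cis - c_trans * exp(-zu)) / (1 - exp(-zu)))
  }
  flux(p_ratio, 1, ionic$cis[["K"]], ionic$trans[["K"]]) +
    flux(1, -1, ionic$cis[["Cl"]], ionic$trans[["Cl"]])
}

#' Estimate the reversal potential from a current-voltage curve
#'
#' `method = "crossing"` interpolates the zero-current crossing linearly
#' between the bracketing voltage pair (with several sign changes, the
#' crossing closest to 0 mV is used).  `method = "poly"` fits a cubic
#' polynomial through all points by least squares and takes its root,
#' which averages the noise of every point into the crossing estimate and
#' is preferable for noisy single sweeps.
#'
#' @param voltages Holding potentials in mV (sorted or not).
#' @param currents Currents at those potentials.
#' @param method `"crossing"` (default) or `"poly"`.
#' @return Reversal potential in mV.
#' @export
estimate_reversal_potential <- function(voltages, currents,
                                        method = c("crossing", "poly")) {
  method <- match.arg(method)
  stopifnot(length(voltages) == length(currents), length(voltages) >= 2)
  o <- order(voltages)
  v <- voltages[o]; i <- currents[o]
  if (method == "poly") {
    if (length(v) < 4) stop("poly method needs >= 4 points", call. = FALSE)
    fit <- stats::lm(i ~ stats::poly(v, 3, raw = TRUE))
    root <- tryCatch(
      stats::uniroot(function(x) {
        stats::predict(fit, data.frame(v = x))
      }, range(v))$root,
      error = function(e) NULL)
    if (is.null(root)) {
      stop_thylakoidr("current-voltage data do not cross zero",
                      "no_crossing")
    }
    return(root)
  }
  s <- sign(i)
  cross <- which(s[-1] * s[-length(s)] <= 0 & (s[-1] != 0 | s[-length(s)] != 0))
  if (!length(cross)) {
    zero <- which(s == 0)
    if (length(zero)) return(v[zero[1]])
    stop_thylakoidr("current-voltage data do not cross zero", "no_crossing")
  }
  vr <- vapply(cross, function(j) {
    if (i[j + 1] == i[j]) (v[j] + v[j + 1]) / 2
    else v[j] - i[j] * (v[j + 1] - v[j]) / (i[j + 1] - i[j])
  }, numeric(1))
  vr[which.min(abs(vr))]
}

#' @export
print.conductance_fit <- function(x, ...) {
  cat("<conductance_fit>\n")
  if (x$branches == "single") {
    cat(sprintf("  gamma (single branch): %.1f pS\n", x$gamma_single))
  } else {
    cat(sprintf("  gamma_pos: %s pS, gamma_neg: %s pS\n",
                ifelse(is.na(x$gamma_pos), "unavailable",
                       sprintf("%.1f", x$gamma_pos)),
                ifelse(is.na(x$gamma_neg), "unavailable",
                       sprintf("%.1f", x$gamma_neg))))
  }
  cat(sprintf("  constrained through V_rev = %g mV\n", x$v_rev))
  invisible(x)
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf("<selectivity_result> V_rev = %.2f mV, P_Cl:P_K = 1:%.3f\n",
              x$v_rev, x$p_ratio))
  invisible(x)
}
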