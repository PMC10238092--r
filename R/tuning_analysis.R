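# Tuning-curve metrics: Gaussian fit to the main ITD peak (best ITD and
# tuning width), half-height frequency bounds and best frequency, frontal
# classification, and the ITD <-> azimuth conversion.

#' Build a tuning curve from trials or rates
#'
#' @param values Stimulus values (strictly increasing).
#' @param rates Mean firing rates (spikes/s), or `NULL` to compute from a
#'   `trial_table` via [curve_from_trials()].
#' @param axis Axis label (`"itd_us"`, `"freq_hz"`, `"ild_db"`).
#' @param n_trials Trials behind each mean (metadata).
#' @return Object of class `tuning_curve`.
#' @export
tuning_curve <- function(values, rates, axis = "itd_us", n_trials = NA) {
  stopifnot(length(values) == length(rates), all(diff(values) > 0),
            all(rates >= 0))
  structure(list(axis = axis, values = as.numeric(values),
                 rates = as.numeric(rates), n_trials = n_trials),
            class = "tuning_curve")
}

#' Average a trial table into a tuning curve
#'
#' Firing rate per stimulus value = mean spike count across trials divided
#' by the counting-window duration.
#'
#' @param tab A `trial_table` (see [simulate_tuning_curves()]).
#' @param trial_dur_s Counting window; defaults to the table's attribute.
#' @return A [tuning_curve()].
#' @export
curve_from_trials <- function(tab, trial_dur_s = attr(tab, "trial_dur_s")) {
  stopifnot(inherits(tab, "trial_table") || is.data.frame(tab))
  if (!is.finite(trial_dur_s)) {
    stop("trial_dur_s unknown; pass it explicitly", call. = FALSE)
  }
  agg <- stats::aggregate(count ~ value, data = as.data.frame(tab), FUN = mean)
  agg <- agg[order(agg$value), ]
  n_tr <- max(table(tab$value))
  tuning_curve(agg$value, agg$count / trial_dur_s,
               axis = if (!is.null(attr(tab, "axis"))) attr(tab, "axis")
                      else "itd_us",
               n_trials = n_tr)
}

#' Gaussian fit to the main peak of an ITD tuning curve
#'
#' The main peak is the contiguous region around the global maximum of the
#' (3-point moving-average smoothed) curve, bounded by the flanking local
#' minima (found by a noise-tolerant outward walk that stops where the
#' curve rises decisively toward a side peak); side peaks fall outside
#' this region and are excluded. A
#' four-parameter Gaussian (amplitude, centre, sd, baseline) is then
#' least-squares fitted to the unsmoothed rates on that region only.
#'
#' @param curve A [tuning_curve()] on the ITD axis with >= 5 points.
#' @return List with `best_itd_us` (fitted centre), `itd_halfwidth_us`
#'   (full width at half height, `2*sqrt(2*log(2))*sd`), and `fit`
#'   diagnostics (`r_squared`, `region` indices, `converged`).
#' @export
fit_itd_main_peak <- function(curve) {
  stopifnot(inherits(curve, "tuning_curve"))
  x <- curve$values
  y <- curve$rates
  n <- length(x)
  if (n < 5L) stop("need >= 5 ITD points", call. = FALSE)
  y_s <- stats::filter(y, rep(1 / 3, 3), sides = 2)
  y_s[1L] <- mean(y[1:2]); y_s[n] <- mean(y[(n - 1L):n])
  y_s <- as.numeric(y_s)
  pk <- which.max(y_s)
  if (pk == 1L || pk == n) {
    stop("no interior peak in ITD curve (monotone response)", call. = FALSE)
  }
  # walk outward to the flanking local minima of the smoothed curve.
  # Tolerant walk: keep descending through small (noise) fluctuations and
  # stop only when the curve rises decisively above the running minimum —
  # the flank of a side peak.
  rise_tol <- 0.15 * diff(range(y_s))
  walk <- function(step) {
    i <- pk
    run_min <- y_s[pk]
    stop_at <- i
    while ((step < 0 && i > 1L) || (step > 0 && i < n)) {
      i <- i + step
      if (y_s[i] < run_min) {
        run_min <- y_s[i]
        stop_at <- i
      } else if (y_s[i] > run_min + rise_tol) {
        break
      }
    }
    stop_at
  }
  lo <- walk(-1L)
  hi <- walk(1L)
  region <- max(1L, min(lo, pk - 2L)):min(n, max(hi, pk + 2L))
  xr <- x[region]; yr <- y[region]
  a0 <- max(yr) - min(yr)
  c0 <- x[pk]
  s0 <- max(diff(range(xr)) / 4, diff(x)[1L])
  b0 <- min(yr)
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(yr ~ a * exp(-(xr - c)^2 / (2 * s^2)) + b,
                 start = list(a = a0, c = c0, s = s0, b = b0),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit) && !isTRUE(fit$convInfo$isConv)) fit <- NULL
  if (is.null(fit)) {
    # fall back to a direct optimizer on the same least-squares objective
    obj <- function(par) {
      sum((yr - (par[1] * exp(-(xr - par[2])^2 / (2 * par[3]^2)) +
                   par[4]))^2)
    }
    op <- stats::optim(c(a0, c0, s0, b0), obj)
    par <- list(a = op$par[1], c = op$par[2], s = abs(op$par[3]),
                b = op$par[4])
    conv <- op$convergence == 0L
  } else {
    cf <- stats::coef(fit)
    par <- list(a = cf[["a"]], c = cf[["c"]], s = abs(cf[["s"]]),
                b = cf[["b"]])
    conv <- TRUE
  }
  pred <- par$a * exp(-(xr - par$c)^2 / (2 * par$s^2)) + par$b
  ss_res <- sum((yr - pred)^2)
  ss_tot <- sum((yr - mean(yr))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  if (!conv || !is.finite(par$c)) {
    stop("Gaussian fit to the ITD main peak did not converge (R^2 = ",
         signif(r2, 3), ")", call. = FALSE)
  }
  list(best_itd_us = par$c,
       itd_halfwidth_us = 2 * sqrt(2 * log(2)) * par$s,
       fit = list(r_squared = r2, region = region, converged = conv,
                  amplitude = par$a, baseline = par$b, sd_us = par$s))
}

#' Half-height frequency metrics
#'
#' The responsive frequency range is the range of frequencies eliciting
#' more than 50% of the maximum response: `freq_lo`/`freq_hi` are the
#' outermost crossings of the half-height level (linearly interpolated
#' between sampled frequencies; sub-threshold dips between them are
#' ignored). Best frequency is the mean of the two bounds; since ICx
#' frequency curves are broad and often flat-topped, the midpoint is the
#' robust summary, not the argmax.
#'
#' @param curve A [tuning_curve()] on the frequency axis.
#' @return List with `freq_lo_hz`, `freq_hi_hz`, `best_freq_hz`,
#'   `freq_range_hz`.
#' @export
frequency_metrics <- function(curve) {
  stopifnot(inherits(curve, "tuning_curve"))
  x <- curve$values
  y <- curve$rates
  if (max(y) <= 0 || diff(range(y)) == 0) {
    stop("degenerate frequency curve (no response modulation)",
         call. = FALSE)
  }
  half <- max(y) / 2
  above <- y > half
  if (!any(above)) stop("no frequencies above half height", call. = FALSE)
  lo_i <- which(above)[1L]
  hi_i <- rev(which(above))[1L]
  lo <- if (lo_i == 1L) x[1L] else {
    x[lo_i - 1L] + (half - y[lo_i - 1L]) / (y[lo_i] - y[lo_i - 1L]) *
      (x[lo_i] - x[lo_i - 1L])
  }
  hi <- if (hi_i == length(x)) x[length(x)] else {
    x[hi_i] + (y[hi_i] - half) / (y[hi_i] - y[hi_i + 1L]) *
      (x[hi_i + 1L] - x[hi_i])
  }
  list(freq_lo_hz = lo, freq_hi_hz = hi,
       best_freq_hz = (lo + hi) / 2, freq_range_hz = hi - lo)
}

#' Frontal classification
#'
#' A neuron is frontally tuned when its best ITD lies within +/- 30 us
#' (about +/- 10 degrees of azimuth); the boundary is inclusive.
#'
#' @param best_itd_us Best ITD in microseconds.
#' @return Logical.
#' @export
classify_frontal <- function(best_itd_us) {
  abs(best_itd_us) <= 30
}

#' Convert ITD to azimuth
#'
#' Uses the barn owl's approximately linear ITD-azimuth relation
#' (~3 us/degree).
#'
#' @param itd_us ITD in microseconds.
#' @param slope_us_per_deg Slope (default 3).
#' @return Azimuth in degrees.
#' @export
itd_to_azimuth <- function(itd_us, slope_us_per_deg = 3) {
  stopifnot(slope_us_per_deg > 0)
  itd_us / slope_us_per_deg
}

#' Summarize one neuron from its ITD and frequency tuning curves
#'
#' @param neuron_id Label.
#' @param group Group label (`"normal"`, `"ruff_removed"`, `"juvenile"`).
#' @param itd_curve,freq_curve [tuning_curve()]s on the respective axes.
#' @param ild_curve Optional ILD [tuning_curve()]; its argmax is reported
#'   as `best_ild_db`.
#' @return One-row data frame with the summary metrics.
#' @export
summarize_neuron <- function(neuron_id, group, itd_curve, freq_curve,
                             ild_curve = NULL) {
  itd <- fit_itd_main_peak(itd_curve)
  fr <- frequency_metrics(freq_curve)
  best_ild <- if (!is.null(ild_curve)) {
    ild_curve$values[which.max(ild_curve$rates)]
  } else NA_real_
  data.frame(neuron_id = neuron_id, group = group,
             best_itd_us = itd$best_itd_us,
             itd_halfwidth_us = itd$itd_halfwidth_us,
             freq_lo_hz = fr$freq_lo_hz, freq_hi_hz = fr$freq_hi_hz,
             best_freq_hz = fr$best_freq_hz,
             freq_range_hz = fr$freq_range_hz,
             best_ild_db = best_ild,
             is_frontal = classify_frontal(itd$best_itd_us))
}
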