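# Model ICx neuron: cyclic (von-Mises-like) ITD tuning at the tone
# frequency, Gaussian ILD tuning, combined multiplicatively and normalized
# into a spatial tuning map over the directions of an HRIR set.
#
# ITD response:  a_max * (exp(cos(2*pi*f*(ITD - mu_n))) - exp(-1))
#                      / (exp(1) - exp(-1))
# ILD response:  a_max * exp(-(ILD - delta_n)^2 / sigma)
# Both peak at a_max; the ITD curve is periodic with period 1/f (side
# peaks at mu_n +/- k/f), the ILD curve is symmetric about delta_n with
# half-height at delta_n +/- sqrt(sigma * ln 2).

#' Model neuron parameters
#'
#' @param f Tone frequency (Hz).
#' @param mu_n Best ITD (seconds; default 0, a frontal neuron).
#' @param delta_n Best ILD (dB; default 0).
#' @param sigma ILD tuning width parameter (dB^2; default 50, i.e.
#'   half-height full width ~ 11.8 dB, typical of ICx ILD curves — the
#'   width is otherwise unconstrained and exposed here).
#' @param a_max Maximum spike rate (spikes/s; default 10).
#' @return List of class `model_neuron_params`.
#' @export
model_neuron_params <- function(f, mu_n = 0, delta_n = 0, sigma = 50,
                                a_max = 10) {
  stopifnot(f > 0, sigma > 0, a_max > 0)
  structure(list(f = f, mu_n = mu_n, delta_n = delta_n, sigma = sigma,
                 a_max = a_max), class = "model_neuron_params")
}

#' ITD response of the model neuron
#'
#' @param itd_s ITD in seconds (vectorized).
#' @param p A [model_neuron_params()].
#' @return Firing rate in spikes/s, within `[0, a_max]`, periodic in ITD
#'   with period `1/f`.
#' @export
itd_response <- function(itd_s, p) {
  stopifnot(inherits(p, "model_neuron_params"))
  p$a_max * (exp(cos(2 * pi * p$f * (itd_s - p$mu_n))) - exp(-1)) /
    (exp(1) - exp(-1))
}

#' ILD response of the model neuron
#'
#' @param ild_db ILD in dB, right minus left (vectorized).
#' @param p A [model_neuron_params()].
#' @return Firing rate in spikes/s, within `(0, a_max]`, symmetric about
#'   `delta_n`.
#' @export
ild_response <- function(ild_db, p) {
  stopifnot(inherits(p, "model_neuron_params"))
  p$a_max * exp(-(ild_db - p$delta_n)^2 / p$sigma)
}

#' Per-frequency ITD/ILD cue field of an HRIR set
#'
#' For each direction: ITD is the lag of the maximum cross-correlation of
#' the two ears' gammatone-filtered (at `frequency_hz`) impulse responses,
#' searched over |tau| <= 1 ms, in microseconds; ILD is the right-minus-
#' left DFT magnitude difference at `frequency_hz` in dB. Narrowband
#' cross-correlation (rather than unwrapped phase) matches the cyclic ITD
#' response of the model neuron, which absorbs the phase ambiguity.
#'
#' @param set An [hrir_set()].
#' @param frequency_hz Tone frequency (below Nyquist).
#' @param max_lag_s ITD search half-width in seconds.
#' @return Object of class `cue_field`: list with `frequency_hz`,
#'   `directions`, `itd_us`, `ild_db` (per direction; `NA` for
#'   zero-energy cells).
#' @export
cue_field <- function(set, frequency_hz, max_lag_s = 1e-3) {
  stopifnot(inherits(set, "hrir_set"))
  fs <- set$sample_rate_hz
  if (frequency_hz >= fs / 2) {
    stop("cue frequency must be below Nyquist", call. = FALSE)
  }
  g <- gammatone_ir(frequency_hz, fs)
  max_lag <- round(max_lag_s * fs)
  n_dir <- nrow(set$directions)
  itd <- ild <- rep(NA_real_, n_dir)
  for (i in seq_len(n_dir)) {
    fl <- fft_convolve(set$left[[i]], g)
    fr <- fft_convolve(set$right[[i]], g)
    if (sum(fl^2) > 1e-20 && sum(fr^2) > 1e-20) {
      itd[i] <- xcorr_peak_lag(fl, fr, max_lag)$lag / fs * 1e6
    }
    ml <- dft_magnitude_at(set$left[[i]], fs, frequency_hz)
    mr <- dft_magnitude_at(set$right[[i]], fs, frequency_hz)
    if (ml > 0 && mr > 0) ild[i] <- 20 * log10(mr) - 20 * log10(ml)
  }
  structure(list(frequency_hz = frequency_hz, directions = set$directions,
                 itd_us = itd, ild_db = ild),
            class = "cue_field")
}

#' Spatial tuning map of a model neuron over a cue field
#'
#' The ITD and ILD responses are evaluated at each direction's cues,
#' multiplied (the established combination rule for ICx neurons), and
#' normalized to a maximum of 1.
#'
#' @param cues A [cue_field()].
#' @param p A [model_neuron_params()] with `p$f == cues$frequency_hz`.
#' @return Object of class `spatial_tuning_map`: list with `frequency_hz`,
#'   `directions`, `response` (normalized, in `[0, 1]`, `NA` for flagged
#'   cells).
#' @export
spatial_tuning_map <- function(cues, p) {
  stopifnot(inherits(cues, "cue_field"),
            inherits(p, "model_neuron_params"))
  if (!isTRUE(all.equal(cues$frequency_hz, p$f))) {
    stop("cue field frequency and neuron frequency differ", call. = FALSE)
  }
  r <- itd_response(cues$itd_us * 1e-6, p) * ild_response(cues$ild_db, p) /
    p$a_max^2
  if (all(!is.finite(r))) {
    stop("all cue-field cells are flagged; empty map", call. = FALSE)
  }
  mx <- max(r, na.rm = TRUE)
  if (mx > 0) r <- r / mx
  structure(list(frequency_hz = cues$frequency_hz,
                 directions = cues$directions, response = r),
            class = "spatial_tuning_map")
}

#' Half-height extent of a spatial tuning map along elevation
#'
#' Width (degrees) of the contiguous region around the peak where the
#' response exceeds half of the map maximum, along the elevation axis at a
#' fixed azimuth. Used to quantify how removing the ruff's
#' elevational ILD cue widens elevational tuning.
#'
#' @param map A [spatial_tuning_map()] on a grid including elevations.
#' @param azimuth_deg Azimuth at which to take the elevation cut.
#' @return Extent in degrees (linear-interpolated half crossings).
#' @export
elevation_halfwidth <- function(map, azimuth_deg = 0) {
  d <- map$directions
  sel <- abs(d$azimuth_deg - azimuth_deg) <= 1e-6
  if (!any(sel)) stop("azimuth not in map grid", call. = FALSE)
  el <- d$elevation_deg[sel]
  r <- map$response[sel]
  o <- order(el)
  el <- el[o]; r <- r[o]
  half_height_extent(el, r)
}

# width of the region above half of the curve's max, outermost crossings
# linearly interpolated; returns the full extent in the axis' units
half_height_extent <- function(x, y) {
  ok <- is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  half <- max(y) / 2
  above <- y >= half
  if (!any(above)) return(0)
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
  hi - lo
}

#' Long-format data frame of a spatial tuning map
#' @param x A `spatial_tuning_map`.
#' @param ... Unused.
#' @return Data frame with one row per direction.
#' @export
as.data.frame.spatial_tuning_map <- function(x, ...) {
  data.frame(freq_hz = x$frequency_hz,
             az_deg = x$directions$azimuth_deg,
             el_deg = x$directions$elevation_deg,
             response_norm = x$response)
}
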