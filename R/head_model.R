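# Parametric "owl head" HRIR generator. Each direction's HRIR pair is a
# per-ear fractional delay (-/+ ITD/2) composed with a minimum-phase filter
# realizing a closed-form magnitude model, so the time cue (ITD) and level
# cues (gain, ILD) are independently and exactly controllable — every
# downstream stage can be checked against the closed form.
#
# The magnitude model captures, qualitatively, what the facial ruff does:
#  * a frontal high-frequency gain lobe (both ears), present only with the
#    ruff intact and removed in the ruff-removed condition;
#  * interaural level difference (ILD) covarying with elevation when the
#    ruff is intact, and only with azimuth (head shadow, doubled) when it
#    is removed;
#  * mild attenuation of low frequencies (< 3 kHz) by the ruff feathers.
# ITD grows linearly with azimuth (~3 us/deg for the barn owl).

#' Parameters of the synthetic owl-head model
#'
#' @param itd_slope_us_per_deg ITD growth with azimuth (default 3 us/deg,
#'   the barn owl's measured relation).
#' @param ruff_gain_db Amplitude A (dB) of the frontal high-frequency gain
#'   lobe contributed by the ruff.
#' @param ruff_az_sigma_deg Angular width (Gaussian sigma, degrees) of the
#'   frontal lobe.
#' @param ruff_freq_lo_hz Frequency where the lobe ramps on; the ramp is a
#'   raised cosine reaching 1 one kilohertz higher.
#' @param shadow_gain_db Azimuthal head-shadow ILD scale (dB at 8 kHz and
#'   90 deg); doubled in the ruff-removed condition.
#' @param elev_ild_gain_db Elevational ILD scale (dB), active only with the
#'   ruff intact (the ruff creates the ILD-elevation cue).
#' @param low_freq_atten_db Attenuation of frequencies below 3 kHz by the
#'   ruff (dB), active only in the normal condition.
#' @param ripple_db Amplitude of a smooth seeded per-owl gain ripple across
#'   frequency and azimuth (individual variation); identical across
#'   conditions at the same seed so condition differences stay exactly the
#'   closed-form ruff terms.
#' @param hrir_len Taps per impulse response (>= 64).
#' @param sample_rate_hz Sampling rate (Hz, >= 20000).
#' @return List of class `head_model_params`.
#' @export
head_model_params <- function(itd_slope_us_per_deg = 3,
                              ruff_gain_db = 10,
                              ruff_az_sigma_deg = 30,
                              ruff_freq_lo_hz = 4000,
                              shadow_gain_db = 6,
                              elev_ild_gain_db = 10,
                              low_freq_atten_db = 3,
                              ripple_db = 1,
                              hrir_len = 256L,
                              sample_rate_hz = 48000) {
  stopifnot(itd_slope_us_per_deg >= 0, hrir_len >= 64L,
            is.finite(ruff_gain_db), is.finite(shadow_gain_db),
            is.finite(elev_ild_gain_db), is.finite(low_freq_atten_db),
            sample_rate_hz >= 20000)
  structure(as.list(environment()), class = "head_model_params")
}

# raised-cosine ramp: 0 below lo, 1 above lo + width
raised_cosine_ramp <- function(f, lo, width = 1000) {
  x <- pmin(pmax((f - lo) / width, 0), 1)
  0.5 * (1 - cos(pi * x))
}

# seeded smooth gain ripple g(f, az) in dB, shared by ears and conditions
head_ripple_fun <- function(params, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_terms <- 3L
  a <- stats::runif(n_terms, 0.3, 1)
  a <- a / sum(a) * params$ripple_db
  per <- stats::runif(n_terms, 1500, 4000)     # ripple period in Hz
  ph <- stats::runif(n_terms, 0, 2 * pi)
  m <- sample(1:3, n_terms, replace = TRUE)    # azimuthal order
  ps <- stats::runif(n_terms, 0, 2 * pi)
  function(f, az) {
    g <- 0
    for (j in seq_len(n_terms)) {
      g <- g + a[j] * cos(2 * pi * f / per[j] + ph[j]) *
        cos(m[j] * az * pi / 180 + ps[j])
    }
    g
  }
}

#' Closed-form magnitude model of the synthetic head
#'
#' The dB gain of each ear as an explicit function of frequency and
#' direction — the ground truth that [make_head_model_hrirs()] realizes as
#' minimum-phase filters. Exposed so tests can compare realized DFT
#' magnitudes against the model.
#'
#' @param params A [head_model_params()].
#' @param condition `"normal"` (ruff intact) or `"ruff_removed"`.
#' @param freq_hz Frequency or vector of frequencies (Hz).
#' @param azimuth_deg,elevation_deg Direction.
#' @param seed Owl seed (selects the individual ripple); `NULL` drops the
#'   ripple term.
#' @return List with numeric vectors `left_db` and `right_db`.
#' @export
head_model_magnitude_db <- function(params, condition, freq_hz,
                                    azimuth_deg, elevation_deg = 0,
                                    seed = NULL) {
  condition <- match.arg(condition, c("normal", "ruff_removed"))
  f <- freq_hz
  az <- azimuth_deg
  el <- elevation_deg
  common <- 0
  if (condition == "normal") {
    lobe <- params$ruff_gain_db *
      raised_cosine_ramp(f, params$ruff_freq_lo_hz) *
      exp(-(az^2 + el^2) / (2 * params$ruff_az_sigma_deg^2))
    lowf <- -params$low_freq_atten_db *
      (1 - raised_cosine_ramp(f, 2500, 500))
    common <- lobe + lowf
  }
  if (!is.null(seed)) {
    common <- common + head_ripple_fun(params, seed)(f, az)
  }
  shadow_scale <- if (condition == "ruff_removed") 2 else 1
  ild <- shadow_scale * params$shadow_gain_db * pmin(f / 8000, 1) *
    sin(az * pi / 180)
  if (condition == "normal") {
    ild <- ild + params$elev_ild_gain_db * pmin(f / 4000, 1) *
      sin(el * pi / 180)
  }
  list(left_db = common - ild / 2, right_db = common + ild / 2)
}

#' Generate a synthetic owl-head HRIR set
#'
#' @param params A [head_model_params()].
#' @param condition `"normal"` or `"ruff_removed"`.
#' @param azimuths_deg,elevations_deg Direction grid (Cartesian product);
#'   default the standard measurement scan, azimuth -160..160 deg in 20 deg
#'   steps at elevation 0.
#' @param owl_id Label stored in the set.
#' @param seed Integer seed selecting the individual owl (gain ripple).
#'   Deterministic: same (params, condition, grid, seed) gives bit-identical
#'   output.
#' @return An [hrir_set()].
#' @export
make_head_model_hrirs <- function(params = head_model_params(),
                                  condition = c("normal", "ruff_removed"),
                                  azimuths_deg = seq(-160, 160, by = 20),
                                  elevations_deg = 0,
                                  owl_id = paste0("synthetic-", seed),
                                  seed = 0L) {
  condition <- match.arg(condition)
  stopifnot(inherits(params, "head_model_params"),
            length(azimuths_deg) >= 1L, length(elevations_deg) >= 1L)
  fs <- params$sample_rate_hz
  if (fs / 2 <= params$ruff_freq_lo_hz + 1000) {
    stop("sample rate too low for the requested ruff frequencies",
         call. = FALSE)
  }
  dirs <- expand.grid(azimuth_deg = azimuths_deg,
                      elevation_deg = elevations_deg,
                      KEEP.OUT.ATTRS = FALSE)
  n_len <- as.integer(params$hrir_len)
  n_fft <- next_pow2(4L * n_len)
  # folded frequency axis for the Hermitian magnitude grid
  k <- 0:(n_fft - 1L)
  f_grid <- pmin(k, n_fft - k) * fs / n_fft
  bulk <- n_len / 4                              # causal headroom, samples
  ripple <- head_ripple_fun(params, seed)

  n <- nrow(dirs)
  left <- vector("list", n)
  right <- vector("list", n)
  for (i in seq_len(n)) {
    az <- dirs$azimuth_deg[i]
    el <- dirs$elevation_deg[i]
    mags <- head_model_magnitude_db(params, condition, f_grid, az, el)
    rip <- ripple(f_grid, az)
    itd_s <- params$itd_slope_us_per_deg * az * 1e-6
    half_delay <- itd_s / 2 * fs                 # samples
    for (ear in c("left", "right")) {
      mag_db <- if (ear == "left") mags$left_db else mags$right_db
      h <- minimum_phase_ir(10^((mag_db + rip) / 20), n_len)
      # positive azimuth: right ear first => left delayed, right advanced
      d <- bulk + if (ear == "left") half_delay else -half_delay
      h <- fractional_delay(h, d, n_fft = n_fft)
      if (ear == "left") left[[i]] <- h else right[[i]] <- h
    }
  }
  hrir_set(owl_id, condition, fs, dirs, left, right)
}

#' Broadband ITD of one direction of an HRIR set
#'
#' Lag of the maximum broadband cross-correlation between the two ears'
#' impulse responses, in microseconds (positive = right ear leads).
#'
#' @param set An [hrir_set()].
#' @param azimuth_deg,elevation_deg Direction to query.
#' @param max_lag_s Search half-width in seconds.
#' @return ITD in microseconds (sample-quantized).
#' @export
broadband_itd_us <- function(set, azimuth_deg, elevation_deg = 0,
                             max_lag_s = 1e-3) {
  i <- direction_index(set, azimuth_deg, elevation_deg)
  if (is.na(i)) stop("direction not in set", call. = FALSE)
  max_lag <- round(max_lag_s * set$sample_rate_hz)
  # x leading y by k samples means y delayed: lag of left vs right > 0
  # when the left ear's signal is a delayed copy => right ear leads.
  pk <- xcorr_peak_lag(set$left[[i]], set$right[[i]], max_lag)
  pk$lag / set$sample_rate_hz * 1e6
}
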