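# Binaural rendering, narrowband interaural phase extraction and circular
# statistics — the primitives under the reliability pipeline.

#' Render a signal through one direction's HRIR pair
#'
#' Full linear convolution of the source signal with the left and right
#' impulse responses; both channels have length
#' `length(signal) + hrir_length - 1`.
#'
#' @param signal Source waveform.
#' @param left_ir,right_ir The direction's impulse responses.
#' @return List with numeric vectors `left` and `right`.
#' @export
binaural_render <- function(signal, left_ir, right_ir) {
  stopifnot(length(left_ir) == length(right_ir))
  list(left = fft_convolve(signal, left_ir),
       right = fft_convolve(signal, right_ir))
}

#' Narrowband interaural phase difference
#'
#' IPD of one frequency band: the lag of the maximum cross-correlation
#' between the left and right band signals, searched over
#' `|tau| <= max_lag_s`, converted to phase at the band centre and wrapped
#' to (-pi, pi]. Positive IPD = right ear leads (package convention).
#'
#' @param left_band,right_band Equal-length band-filtered signals.
#' @param center_freq_hz Band centre frequency (Hz).
#' @param fs_hz Sampling rate (Hz).
#' @param max_lag_s Lag search half-width (default 1 ms, generously covering
#'   the owl's physiological ITD range).
#' @return IPD in radians, or `NA` if either band has (near-)zero energy.
#' @export
band_ipd <- function(left_band, right_band, center_freq_hz, fs_hz,
                     max_lag_s = 1e-3) {
  e_l <- sum(left_band^2)
  e_r <- sum(right_band^2)
  if (e_l <= 1e-20 || e_r <= 1e-20) return(NA_real_)
  max_lag <- round(max_lag_s * fs_hz)
  # parabolic sub-sample refinement: keeps the IPD continuous instead of
  # quantized to 2*pi*fc/fs steps (pi/2 per sample at fc = fs/4)
  pk <- xcorr_peak_lag(left_band, right_band, max_lag, refine = TRUE)
  tau_s <- pk$lag / fs_hz            # t_left - t_right at the peak
  wrap_angle(2 * pi * center_freq_hz * tau_s)
}

#' Circular standard deviation
#'
#' The Mardia circular standard deviation `sqrt(-2 * log(Rbar))`, where
#' `Rbar` is the mean resultant length of the angles. Invariant to global
#' rotation and to permutation of the angles.
#'
#' @param angles Angles in radians; `NA`s are dropped.
#' @return Standard deviation in radians; `Inf` when the resultant vanishes
#'   (uniformly dispersed angles); 0 when all angles coincide.
#' @export
circular_sd <- function(angles) {
  angles <- angles[is.finite(angles)]
  if (length(angles) < 2L) {
    stop("circular_sd needs at least 2 finite angles", call. = FALSE)
  }
  rbar <- Mod(mean(exp(1i * angles)))
  if (rbar <= .Machine$double.eps^0.5) return(Inf)
  if (rbar >= 1) return(0)
  sqrt(-2 * log(rbar))
}
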