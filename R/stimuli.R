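# Stimulus generators for the reliability pipeline: flat-spectrum band
# noise (the default target/masker token) and a spectro-temporally rich
# vocalization surrogate standing in for a natural prey call.

#' Flat-spectrum band-limited noise
#'
#' Random-phase noise with flat magnitude inside `[band_lo_hz, band_hi_hz]`
#' and zero outside, normalized to unit RMS. Deterministic per seed.
#'
#' @param band_lo_hz,band_hi_hz Band edges in Hz; must satisfy
#'   `0 < band_lo_hz < band_hi_hz < sample_rate_hz / 2`.
#' @param duration_s Duration in seconds.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param seed Integer seed.
#' @return Numeric vector of `round(duration_s * sample_rate_hz)` samples.
#' @export
make_broadband_stimulus <- function(band_lo_hz = 500, band_hi_hz = 10000,
                                    duration_s = 0.1,
                                    sample_rate_hz = 48000, seed = 0L) {
  if (!(band_lo_hz > 0 && band_lo_hz < band_hi_hz &&
        band_hi_hz < sample_rate_hz / 2)) {
    stop("need 0 < band_lo_hz < band_hi_hz < sample_rate_hz/2",
         call. = FALSE)
  }
  n <- round(duration_s * sample_rate_hz)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  half <- n %/% 2L
  freqs <- (seq_len(half - 1L)) * sample_rate_hz / n   # positive bins
  mag <- as.numeric(freqs >= band_lo_hz & freqs <= band_hi_hz)
  phases <- stats::runif(half - 1L, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = phases)
  full <- c(0, spec,
            if (n %% 2L == 0L) 0,       # Nyquist bin
            Conj(rev(spec)))
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Vocalization surrogate
#'
#' A synthetic stand-in for a natural broadband vocalization (e.g. a prey
#' scream): a downward-chirping harmonic stack with amplitude modulation
#' over a broadband noise floor, giving spectral energy across the whole
#' 0.5-10 kHz hearing range while remaining spectro-temporally structured,
#' unlike flat noise. Unit RMS; deterministic per seed.
#'
#' @param duration_s Duration in seconds (default 0.1, i.e. 100 ms).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param seed Integer seed.
#' @return Numeric vector of `round(duration_s * sample_rate_hz)` samples.
#' @export
make_vocalization_surrogate <- function(duration_s = 0.1,
                                        sample_rate_hz = 48000, seed = 0L) {
  stopifnot(duration_s > 0)
  n <- round(duration_s * sample_rate_hz)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  t <- (seq_len(n) - 1L) / sample_rate_hz
  dur <- n / sample_rate_hz
  # fundamental chirps 1.4 -> 0.7 kHz; harmonics tile the band up to 10 kHz
  f0 <- 1400 * (0.5)^(t / dur)
  phase0 <- 2 * pi * cumsum(f0) / sample_rate_hz
  x <- numeric(n)
  n_harm <- 14L
  for (k in seq_len(n_harm)) {
    amp <- k^(-0.3) * stats::runif(1, 0.7, 1.3)
    x <- x + amp * sin(k * phase0 + stats::runif(1, 0, 2 * pi))
  }
  # slow amplitude modulation (screech roughness)
  x <- x * (1 + 0.5 * sin(2 * pi * 30 * t + stats::runif(1, 0, 2 * pi)))
  noise <- make_broadband_stimulus(500, min(10000, sample_rate_hz / 2 - 1),
                                   duration_s, sample_rate_hz,
                                   seed = seed + 1013L)
  x <- x / sqrt(mean(x^2)) + 0.3 * noise
  x / sqrt(mean(x^2))
}

# Save/restore .Random.seed so generators with explicit seeds do not
# clobber the caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
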