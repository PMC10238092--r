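# Shared fixtures. Heavy objects (synthetic heads, reliability maps) are
# memoized in this environment so multiple test files can reuse them; all
# fixtures are generated in code, nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# small, fast head-model parameterization used across tests: 24 kHz keeps
# FFT sizes half of the 48 kHz default while leaving the full 1-10 kHz
# analysis range below Nyquist
test_head_params <- function(...) {
  head_model_params(sample_rate_hz = 24000, hrir_len = 128L, ...)
}

test_head <- function(condition = "normal", seed = 1L,
                      azimuths_deg = seq(-160, 160, by = 20),
                      elevations_deg = 0) {
  key <- paste("head", condition, seed,
               paste(range(azimuths_deg), collapse = "_"),
               length(azimuths_deg), length(elevations_deg))
  memo(key, make_head_model_hrirs(test_head_params(), condition,
                                  azimuths_deg = azimuths_deg,
                                  elevations_deg = elevations_deg,
                                  seed = seed))
}

# a trivial two-direction set with impulse HRIRs, for I/O round trips
tiny_impulse_set <- function(n_dir = 2L, len = 64L, fs = 48000) {
  dirs <- data.frame(azimuth_deg = seq(0, by = 20, length.out = n_dir),
                     elevation_deg = 0)
  imp <- function(k) { h <- numeric(len); h[k] <- 1; h }
  hrir_set("tiny", "synthetic_custom", fs, dirs,
           left = lapply(seq_len(n_dir), function(i) imp(1L)),
           right = lapply(seq_len(n_dir), function(i) imp(1L)))
}
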