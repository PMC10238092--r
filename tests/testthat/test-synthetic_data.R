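# Synthetic head model, stimulus generators, and the Poisson tuning-curve
# simulator.

test_that("head-model ITD is linear in azimuth at the stated slope", {
  s <- test_head("normal")
  fs <- s$sample_rate_hz
  one_sample_us <- 1e6 / fs
  expect_lt(abs(broadband_itd_us(s, 0)), one_sample_us)
  expect_lt(abs(broadband_itd_us(s, 60) - 180), one_sample_us)
  # linearity across the grid (within one sample period per azimuth step)
  az <- seq(-160, 160, by = 20)
  itd <- vapply(az, function(a) broadband_itd_us(s, a), 1)
  fit <- stats::lm(itd ~ az)
  expect_equal(unname(coef(fit)[2]), 3, tolerance = 0.02)
  expect_lt(max(abs(stats::resid(fit))), one_sample_us)
})

test_that("mirrored azimuth negates ITD and azimuthal ILD", {
  s <- test_head("ruff_removed")
  for (a in c(20, 60, 120)) {
    expect_equal(broadband_itd_us(s, a), -broadband_itd_us(s, -a))
  }
  cf <- cue_field(s, 6000)
  i_p <- direction_index(s, 60); i_m <- direction_index(s, -60)
  expect_equal(cf$ild_db[i_p], -cf$ild_db[i_m], tolerance = 0.1)
  expect_gt(cf$ild_db[i_p], 1)   # right source -> right ear louder
})

test_that("realized magnitudes match the closed-form model; ruff lobe", {
  p <- test_head_params()
  s_n <- test_head("normal", seed = 3)
  s_r <- test_head("ruff_removed", seed = 3)
  freqs <- c(1500, 3000, 4500, 6000, 7500)
  for (a in c(0, 40)) {
    i <- direction_index(s_n, a)
    for (set_cond in list(list(s_n, "normal"), list(s_r, "ruff_removed"))) {
      s <- set_cond[[1]]; cond <- set_cond[[2]]
      mm <- head_model_magnitude_db(p, cond, freqs, a, 0, seed = 3)
      left_db <- 20 * log10(owlcue:::dft_magnitude_at(
        s$left[[i]], p$sample_rate_hz, freqs, n_fft = 8192L))
      expect_equal(left_db, mm$left_db, tolerance = 0.2)
    }
  }
  # condition difference at (az 0, 6 kHz) is exactly the lobe + low-freq
  # terms of the closed form, within filter-design tolerance 0.5 dB
  g_n <- gain_map(s_n, c(2000, 6000))
  g_r <- gain_map(s_r, c(2000, 6000))
  i0 <- direction_index(s_n, 0)
  d6k <- unname(g_n$gain_db[2, i0] - g_r$gain_db[2, i0])
  expect_equal(d6k, p$ruff_gain_db, tolerance = 0.5)      # w(6 kHz) = 1
  d2k <- unname(g_n$gain_db[1, i0] - g_r$gain_db[1, i0])
  expect_equal(d2k, -p$low_freq_atten_db, tolerance = 0.5)
})

test_that("head model is deterministic and owl seeds differ", {
  a <- make_head_model_hrirs(test_head_params(), "normal",
                             azimuths_deg = c(0, 20), seed = 5)
  b <- make_head_model_hrirs(test_head_params(), "normal",
                             azimuths_deg = c(0, 20), seed = 5)
  expect_identical(a$left, b$left)
  c2 <- make_head_model_hrirs(test_head_params(), "normal",
                              azimuths_deg = c(0, 20), seed = 6)
  expect_false(identical(a$left, c2$left))
  expect_error(
    make_head_model_hrirs(head_model_params(sample_rate_hz = 2e4,
                                            ruff_freq_lo_hz = 9500),
                          "normal"),
    "sample rate too low")
})

test_that("broadband stimulus is flat in band, silent out of band", {
  fs <- 48000
  x <- make_broadband_stimulus(500, 10000, 0.1, fs, seed = 11)
  expect_length(x, 4800)
  expect_equal(sqrt(mean(x^2)), 1, tolerance = 1e-9)
  expect_identical(x, make_broadband_stimulus(500, 10000, 0.1, fs,
                                              seed = 11))
  # periodogram oracle
  spec <- Mod(stats::fft(x))^2 / length(x)
  freqs <- (seq_along(x) - 1) * fs / length(x)
  in_band <- freqs >= 600 & freqs <= 9900
  out_band <- freqs > 11000 & freqs < fs / 2
  # flat: average PSD in octave sub-bands within 1 dB of each other
  octs <- cut(freqs[in_band], c(600, 1200, 2400, 4800, 9900))
  band_means <- tapply(spec[in_band], octs, mean)
  expect_lt(max(10 * log10(band_means / mean(band_means))), 1)
  expect_lt(10 * log10(mean(spec[out_band]) / mean(spec[in_band])), -40)
  expect_error(make_broadband_stimulus(5000, 1000, 0.1, fs), "band")
})

test_that("vocalization surrogate spans the hearing range", {
  fs <- 48000
  x <- make_vocalization_surrogate(0.1, fs, seed = 2)
  expect_length(x, 4800)
  expect_equal(sqrt(mean(x^2)), 1, tolerance = 1e-9)
  expect_identical(x, make_vocalization_surrogate(0.1, fs, seed = 2))
  spec <- Mod(stats::fft(x))^2
  freqs <- (seq_along(x) - 1) * fs / length(x)
  octaves <- list(c(500, 1000), c(1000, 2000), c(2000, 4000),
                  c(4000, 8000))
  e <- vapply(octaves, function(b) {
    mean(spec[freqs >= b[1] & freqs < b[2]])
  }, 1)
  # energy present (> -30 dB re the strongest octave) in every octave
  expect_gt(min(10 * log10(e / max(e))), -30)
})

test_that("Poisson tuning simulator matches ground-truth rates and noise", {
  gt <- neuron_ground_truth(best_itd_us = 50, best_freq_hz = 5000,
                            freq_lo_hz = 3500, freq_hi_hz = 6500,
                            side_peak_ratio = 0.5, n_trials = 10000L)
  vals <- seq(-300, 300, by = 50)
  tab <- simulate_tuning_curves(gt, "itd_us", vals, seed = 9)
  emp <- tapply(tab$count, tab$value, mean) / gt$trial_dur_s
  truth <- ground_truth_rate(gt, "itd_us", vals)
  # law of large numbers: within 3 Poisson standard errors
  se <- sqrt(truth / (gt$trial_dur_s * gt$n_trials))
  expect_true(all(abs(emp - truth) < 3.5 * se + 1e-9))
  # Poisson property: per-cell variance ~ mean of counts
  v <- tapply(tab$count, tab$value, var)
  m <- tapply(tab$count, tab$value, mean)
  keep <- m > 0.5
  expect_true(all(abs(v[keep] / m[keep] - 1) < 0.15))

  # side peaks: at best_itd +/- period, amplitude ratio ~ side_peak_ratio
  period_us <- 1e6 / gt$best_freq_hz   # 200 us
  r_main <- ground_truth_rate(gt, "itd_us", gt$best_itd_us)
  r_side <- ground_truth_rate(gt, "itd_us", gt$best_itd_us + period_us)
  # tiny deviation from 0.5 comes from the opposite side peak's Gaussian
  # tail leaking under the main peak
  expect_equal((r_side - gt$base_rate) / (r_main - gt$base_rate), 0.5,
               tolerance = 1e-4)
  # side_peak_ratio 0 -> single-peaked
  gt0 <- neuron_ground_truth(side_peak_ratio = 0)
  r <- ground_truth_rate(gt0, "itd_us", seq(-400, 400, by = 5))
  peaks <- which(diff(sign(diff(r))) == -2) + 1L
  expect_equal(length(peaks), 1L)

  # frequency trapezoid: half-height exactly at the stated bounds
  r_bounds <- ground_truth_rate(gt, "freq_hz",
                                c(gt$freq_lo_hz, gt$freq_hi_hz))
  expect_equal(r_bounds,
               rep(gt$base_rate + (gt$max_rate - gt$base_rate) / 2, 2))
  expect_identical(simulate_tuning_curves(gt, "freq_hz", seed = 3)$count,
                   simulate_tuning_curves(gt, "freq_hz", seed = 3)$count)
})

test_that("trial tables round-trip through TSV + JSON sidecar", {
  gt <- neuron_ground_truth(n_trials = 5L)
  tab <- simulate_tuning_curves(gt, "freq_hz",
                                values = seq(1000, 9000, by = 500),
                                seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trial_table(tab, path)
  tab2 <- read_trial_table(path)
  expect_equal(tab2$count, tab$count)
  expect_equal(attr(tab2, "axis"), "freq_hz")
  expect_equal(attr(tab2, "trial_dur_s"), gt$trial_dur_s)
  expect_equal(attr(tab2, "ground_truth")$best_freq_hz, gt$best_freq_hz)
})
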