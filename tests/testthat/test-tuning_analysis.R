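# Tuning-curve metrics: Gaussian main-peak fit, half-height frequency
# bounds, frontal classification, ITD-azimuth conversion.

test_that("noiseless Gaussian ITD curve is recovered exactly", {
  x <- seq(-200, 200, by = 10)
  y <- 50 * exp(-(x - 40)^2 / (2 * 30^2)) + 2
  fit <- fit_itd_main_peak(tuning_curve(x, y, axis = "itd_us"))
  expect_equal(fit$best_itd_us, 40, tolerance = 0.5)
  expect_equal(fit$itd_halfwidth_us, 2 * sqrt(2 * log(2)) * 30,
               tolerance = 1)
  expect_gt(fit$fit$r_squared, 0.999)
})

test_that("side peaks are excluded from the fitted region", {
  gt <- neuron_ground_truth(best_itd_us = 0, best_freq_hz = 5000,
                            freq_lo_hz = 4000, freq_hi_hz = 6000,
                            side_peak_ratio = 0.6, itd_env_sigma_us = 30)
  x <- seq(-300, 300, by = 10)
  y <- ground_truth_rate(gt, "itd_us", x)    # side peaks at +/- 200 us
  fit <- fit_itd_main_peak(tuning_curve(x, y, axis = "itd_us"))
  expect_equal(fit$best_itd_us, 0, tolerance = 2)
  # fitted region stays inside the flanking minima (side peaks excluded)
  expect_true(all(abs(x[fit$fit$region]) < 200))
})

test_that("degenerate ITD curves raise errors", {
  x <- seq(-100, 100, by = 10)
  expect_error(fit_itd_main_peak(tuning_curve(x, seq_along(x),
                                              axis = "itd_us")),
               "peak")
  expect_error(fit_itd_main_peak(tuning_curve(1:4, c(0, 1, 0, 0))),
               ">= 5")
})

test_that("Poisson ITD recovery: within 10 us of truth in >= 95% of fits", {
  # simulation-based calibration: 200 seeded replicates, 20 trials/value
  gt <- neuron_ground_truth(best_itd_us = 40, best_freq_hz = 5000,
                            freq_lo_hz = 4000, freq_hi_hz = 6000,
                            max_rate = 60, n_trials = 20L)
  errs <- vapply(seq_len(200), function(k) {
    tab <- simulate_tuning_curves(gt, "itd_us", seed = 1000 + k)
    fit <- tryCatch(fit_itd_main_peak(curve_from_trials(tab)),
                    error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    abs(fit$best_itd_us - gt$best_itd_us)
  }, 1)
  expect_gte(mean(errs <= 10), 0.95)
})

test_that("frequency_metrics matches hand interpolation and oracle", {
  # hand computation: rates 0,2,10,8,4,1 at 2-7 kHz, half-height 5
  cv <- tuning_curve(seq(2000, 7000, by = 1000), c(0, 2, 10, 8, 4, 1),
                     axis = "freq_hz")
  fm <- frequency_metrics(cv)
  expect_equal(fm$freq_lo_hz, 3375)
  expect_equal(fm$freq_hi_hz, 5750)
  expect_equal(fm$best_freq_hz, 4562.5)
  expect_equal(fm$freq_range_hz, 2375)

  # symmetric triangle: best = peak frequency
  x <- seq(1000, 9000, by = 500)
  tri <- pmax(0, 1 - abs(x - 5000) / 3000)
  expect_equal(frequency_metrics(tuning_curve(x, tri,
                                              axis = "freq_hz"))$best_freq_hz,
               5000)

  # curve above half max except at the endpoints: interpolated endpoint
  # crossings, checked against a brute-force crossing scan
  y <- c(1, 8, 9, 10, 9.5, 8.5, 2)
  x2 <- seq(2000, 8000, by = 1000)
  fm2 <- frequency_metrics(tuning_curve(x2, y, axis = "freq_hz"))
  brute <- function(x, y, half) {
    xs <- seq(min(x), max(x), by = 0.5)
    ys <- approx(x, y, xs)$y
    range(xs[ys > half])
  }
  b <- brute(x2, y, 5)
  expect_equal(fm2$freq_lo_hz, b[1], tolerance = 1)
  expect_equal(fm2$freq_hi_hz, b[2], tolerance = 1)

  # invariance to uniform rescaling; equivariance to frequency shifts
  fm3 <- frequency_metrics(tuning_curve(x2, 7.3 * y, axis = "freq_hz"))
  expect_equal(fm3, fm2)
  fm4 <- frequency_metrics(tuning_curve(x2 + 500, y, axis = "freq_hz"))
  expect_equal(fm4$best_freq_hz, fm2$best_freq_hz + 500)

  expect_error(frequency_metrics(tuning_curve(x2, rep(3, 7),
                                              axis = "freq_hz")),
               "degenerate")
})

test_that("frontal classification boundary is inclusive at 30 us", {
  expect_true(classify_frontal(0))
  expect_true(classify_frontal(30))
  expect_true(classify_frontal(-30))
  expect_false(classify_frontal(-45))
  expect_false(classify_frontal(30.001))
})

test_that("itd_to_azimuth uses the 3 us/deg relation", {
  expect_equal(itd_to_azimuth(30), 10)
  expect_equal(itd_to_azimuth(0), 0)
  expect_equal(itd_to_azimuth(230), 76.66667, tolerance = 1e-5)
  expect_equal(itd_to_azimuth(30, slope_us_per_deg = 2), 15)
})

test_that("parameter recovery across the ground-truth roster", {
  # best ITD in {0, 50, 100, 200} us, bounds spanning 2-8 kHz, 20 trials
  grid <- expand.grid(itd = c(0, 50, 100, 200),
                      f = c(3000, 5000, 7000))
  errs <- t(mapply(function(itd, f, k) {
    gt <- neuron_ground_truth(best_itd_us = itd, best_freq_hz = f,
                              freq_lo_hz = f - 1000, freq_hi_hz = f + 1000,
                              max_rate = 60, n_trials = 20L)
    itd_tab <- simulate_tuning_curves(gt, "itd_us", seed = 7000 + k)
    frq_tab <- simulate_tuning_curves(gt, "freq_hz", seed = 8000 + k)
    s <- summarize_neuron("n", "normal", curve_from_trials(itd_tab),
                          curve_from_trials(frq_tab))
    c(d_itd = abs(s$best_itd_us - itd), d_f = abs(s$best_freq_hz - f))
  }, grid$itd, grid$f, seq_len(nrow(grid))))
  expect_lte(median(errs[, "d_itd"]), 10)
  expect_lte(median(errs[, "d_f"]), 150)
})

test_that("lower best frequency implies wider fitted ITD halfwidth", {
  # the physiological trend: ITD tuning width scales with 1/frequency.
  # Ground truth encodes it via the envelope sigma ~ 0.25 periods (wide
  # enough to be physiological, narrow enough that the side peaks at one
  # full period stay separable from the main peak)
  fs <- c(2500, 4000, 5500, 7000)
  widths <- vapply(seq_along(fs), function(i) {
    f <- fs[i]
    gt <- neuron_ground_truth(best_itd_us = 0, best_freq_hz = f,
                              freq_lo_hz = f - 1000, freq_hi_hz = f + 1000,
                              itd_env_sigma_us = 0.25 * 1e6 / f,
                              max_rate = 60, n_trials = 20L)
    # average the fitted width over seeds to beat single-fit noise
    mean(vapply(1:6, function(r) {
      tab <- simulate_tuning_curves(gt, "itd_us", seed = 40 + 10L * i + r)
      fit_itd_main_peak(curve_from_trials(tab))$itd_halfwidth_us
    }, 1))
  }, 1)
  expect_true(all(diff(widths) < 0))   # monotone decreasing with frequency
})
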