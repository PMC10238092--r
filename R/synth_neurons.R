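# Poisson single-unit simulator with known ground truth. Rate functions:
#  * ITD: baseline + (max-base) * [Gaussian main peak at best_itd +
#    side_peak_ratio * Gaussian side peaks at best_itd +/- 1/best_freq],
#    capped at the max rate — the periodic side peaks of ICx neurons with
#    suppressed amplitude.
#  * frequency: trapezoid whose half-height crossings sit exactly at
#    (freq_lo, freq_hi), so the half-height metrics have closed-form truth.
#  * ILD: Gaussian around ild_best.
# Spike counts are Poisson(rate * trial_dur) per trial.

#' Ground-truth parameters of a synthetic neuron
#'
#' @param best_itd_us Main-peak ITD (microseconds).
#' @param best_freq_hz Best frequency (Hz); also sets the side-peak spacing
#'   `1/best_freq`.
#' @param freq_lo_hz,freq_hi_hz Half-height bounds of the trapezoidal
#'   frequency profile (must bracket `best_freq_hz`).
#' @param ild_best_db Best ILD (dB).
#' @param ild_sigma ILD tuning width parameter (dB^2).
#' @param itd_env_sigma_us Gaussian sigma of the main ITD peak
#'   (microseconds).
#' @param side_peak_ratio Side-peak amplitude as a fraction of the main
#'   peak, in `[0, 1)`.
#' @param base_rate,max_rate Baseline and peak firing rates (spikes/s).
#' @param n_trials Repetitions per stimulus value.
#' @param trial_dur_s Spike-counting window per trial (seconds).
#' @return List of class `neuron_ground_truth`.
#' @export
neuron_ground_truth <- function(best_itd_us = 0, best_freq_hz = 5000,
                                freq_lo_hz = 4000, freq_hi_hz = 6000,
                                ild_best_db = 0, ild_sigma = 50,
                                itd_env_sigma_us = 40,
                                side_peak_ratio = 0.5,
                                base_rate = 1, max_rate = 60,
                                n_trials = 20L, trial_dur_s = 0.1) {
  stopifnot(freq_lo_hz < best_freq_hz, best_freq_hz < freq_hi_hz,
            side_peak_ratio >= 0, side_peak_ratio < 1,
            max_rate > base_rate, base_rate >= 0,
            itd_env_sigma_us > 0, ild_sigma > 0, n_trials >= 1L,
            trial_dur_s > 0)
  structure(as.list(environment()), class = "neuron_ground_truth")
}

#' Ground-truth firing rate of a synthetic neuron
#'
#' @param gt A [neuron_ground_truth()].
#' @param axis One of `"itd_us"`, `"freq_hz"`, `"ild_db"`.
#' @param values Stimulus values on that axis.
#' @return Rates in spikes/s.
#' @export
ground_truth_rate <- function(gt, axis = c("itd_us", "freq_hz", "ild_db"),
                              values) {
  stopifnot(inherits(gt, "neuron_ground_truth"))
  axis <- match.arg(axis)
  span <- gt$max_rate - gt$base_rate
  switch(axis,
    itd_us = {
      period_us <- 1e6 / gt$best_freq_hz
      gpeak <- function(center) {
        exp(-(values - center)^2 / (2 * gt$itd_env_sigma_us^2))
      }
      shape <- gpeak(gt$best_itd_us) +
        gt$side_peak_ratio * (gpeak(gt$best_itd_us + period_us) +
                              gpeak(gt$best_itd_us - period_us))
      gt$base_rate + span * pmin(shape, 1)
    },
    freq_hz = {
      # trapezoid: half-height exactly at freq_lo and freq_hi; full height
      # on the inner half of each shoulder
      lo <- gt$freq_lo_hz; hi <- gt$freq_hi_hz
      rise <- (hi - lo) / 4            # shoulder width (half-height at mid)
      up <- pmin(pmax((values - (lo - rise)) / (2 * rise), 0), 1)
      down <- pmin(pmax(((hi + rise) - values) / (2 * rise), 0), 1)
      gt$base_rate + span * pmin(up, down)
    },
    ild_db = {
      gt$base_rate +
        span * exp(-(values - gt$ild_best_db)^2 / (2 * gt$ild_sigma))
    })
}

#' Simulate Poisson spike-count tuning trials
#'
#' @param gt A [neuron_ground_truth()].
#' @param axis Stimulus axis (`"itd_us"`, `"freq_hz"`, `"ild_db"`).
#' @param values Stimulus values; defaults per axis: ITD -300..300 us in
#'   10 us steps, frequency 500-10000 Hz in 200 Hz steps (the tonal
#'   protocol), ILD -20..20 dB in 2 dB steps.
#' @param seed Integer seed; deterministic per seed.
#' @return Object of class `trial_table`: data frame with columns
#'   `axis`, `value`, `trial`, `count`, plus attributes `axis`,
#'   `trial_dur_s` and `ground_truth`.
#' @export
simulate_tuning_curves <- function(gt,
                                   axis = c("itd_us", "freq_hz", "ild_db"),
                                   values = NULL, seed = 0L) {
  stopifnot(inherits(gt, "neuron_ground_truth"))
  axis <- match.arg(axis)
  if (is.null(values)) {
    values <- switch(axis,
                     itd_us = seq(-300, 300, by = 10),
                     freq_hz = seq(500, 10000, by = 200),
                     ild_db = seq(-20, 20, by = 2))
  }
  rates <- ground_truth_rate(gt, axis, values)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  counts <- stats::rpois(length(values) * gt$n_trials,
                         lambda = rep(rates, each = gt$n_trials) *
                           gt$trial_dur_s)
  tab <- data.frame(axis = axis,
                    value = rep(values, each = gt$n_trials),
                    trial = rep(seq_len(gt$n_trials), length(values)),
                    count = counts)
  structure(tab, axis = axis, trial_dur_s = gt$trial_dur_s,
            ground_truth = gt, class = c("trial_table", "data.frame"))
}

#' Write / read a trial table as TSV with a JSON ground-truth sidecar
#'
#' @param tab A `trial_table`.
#' @param path TSV path; the sidecar goes to `<path>.json`.
#' @return `path` invisibly (write) or a `trial_table` (read; the sidecar
#'   is optional on read).
#' @export
write_trial_table <- function(tab, path) {
  stopifnot(inherits(tab, "trial_table"))
  utils::write.table(as.data.frame(tab), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  side <- list(axis = attr(tab, "axis"),
               trial_dur_s = attr(tab, "trial_dur_s"),
               ground_truth = unclass(attr(tab, "ground_truth")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  side_path <- paste0(path, ".json")
  axis <- tab$axis[1L]
  trial_dur <- NA_real_
  gt <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    axis <- side$axis
    trial_dur <- side$trial_dur_s
    if (!is.null(side$ground_truth)) {
      gt <- structure(side$ground_truth, class = "neuron_ground_truth")
    }
  }
  structure(tab, axis = axis, trial_dur_s = trial_dur, ground_truth = gt,
            class = c("trial_table", "data.frame"))
}
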