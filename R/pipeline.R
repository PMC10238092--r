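# End-to-end orchestration: synthesize (or load) HRIR sets, run the
# reliability / gain / model-neuron stages, simulate a neuron roster,
# extract tuning metrics and compare groups — all from one config with a
# single global seed fanned out per stage, so stages can be rerun
# independently and reproducibly. Outputs are plain TSV/JSON; the run
# manifest records a content hash per file.

#' Pipeline configuration
#'
#' @param out_dir Output directory.
#' @param n_owls Synthetic owls per condition.
#' @param head Head-model parameters ([head_model_params()]).
#' @param azimuths_deg Azimuth grid for the synthetic heads.
#' @param fb Filterbank spec ([filterbank_spec()]).
#' @param reliability Reliability config ([reliability_config()]); its
#'   seed field is overridden by the fanned-out stage seed.
#' @param gain_freqs_hz Frequencies for the gain stage.
#' @param map_freqs_hz Tone frequencies for the model-neuron maps
#'   (default 3-7 kHz in 1 kHz steps, the range where tuning changes).
#' @param roster List of [neuron_ground_truth()] objects with a `group`
#'   attribute each, or `NULL` for the default 8-neuron demo roster.
#' @param seed Global integer seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "owlcue-run",
                            n_owls = 3L,
                            head = head_model_params(),
                            azimuths_deg = seq(-160, 160, by = 20),
                            fb = filterbank_spec(),
                            reliability = reliability_config(
                              n_repetitions = 2L),
                            gain_freqs_hz = seq(500, 10000, by = 200),
                            map_freqs_hz = seq(3000, 7000, by = 1000),
                            roster = NULL,
                            seed = 0L) {
  if (is.null(roster)) roster <- default_roster()
  structure(list(out_dir = out_dir, n_owls = as.integer(n_owls),
                 head = head, azimuths_deg = azimuths_deg, fb = fb,
                 reliability = reliability, gain_freqs_hz = gain_freqs_hz,
                 map_freqs_hz = map_freqs_hz, roster = roster,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Scalar fields override the defaults of [pipeline_config()]; nested
#' `head`, `fb` and `reliability` objects override the corresponding
#' constructor defaults field-wise.
#'
#' @param path JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (nm in c("out_dir", "n_owls", "azimuths_deg", "gain_freqs_hz",
               "map_freqs_hz", "seed")) {
    if (!is.null(j[[nm]])) args[[nm]] <- j[[nm]]
  }
  if (!is.null(j$head)) args$head <- do.call(head_model_params, j$head)
  if (!is.null(j$fb)) args$fb <- do.call(filterbank_spec, j$fb)
  if (!is.null(j$reliability)) {
    args$reliability <- do.call(reliability_config, j$reliability)
  }
  if (!is.null(j$roster)) {
    args$roster <- lapply(seq_len(nrow(j$roster)), function(i) {
      row <- as.list(j$roster[i, ])
      grp <- row$group; row$group <- NULL
      gt <- do.call(neuron_ground_truth, row)
      attr(gt, "group") <- grp
      gt
    })
  }
  do.call(pipeline_config, args)
}

# default 8-neuron demo roster: frontal neurons per group with the group
# structure of the recorded populations (normal high, ruff-removed low,
# juvenile intermediate/heterogeneous), plus two peripheral neurons
default_roster <- function() {
  mk <- function(group, best_itd, best_f, lo, hi, width = 40) {
    gt <- neuron_ground_truth(best_itd_us = best_itd, best_freq_hz = best_f,
                              freq_lo_hz = lo, freq_hi_hz = hi,
                              itd_env_sigma_us = width)
    attr(gt, "group") <- group
    gt
  }
  list(mk("normal", 0, 6000, 4750, 7250),
       mk("normal", 20, 5800, 4500, 7100),
       mk("normal", 150, 3500, 2500, 4500, width = 60),
       mk("ruff_removed", 0, 4400, 3300, 5500),
       mk("ruff_removed", -25, 4700, 3500, 5900),
       mk("ruff_removed", 120, 3800, 2800, 4800, width = 55),
       mk("juvenile", 10, 5000, 3400, 6600, width = 50),
       mk("juvenile", -15, 4800, 3000, 6600, width = 50))
}

# counter-based per-stage seed fan-out (kept well below 2^31)
stage_seed <- function(seed, stage) {
  offsets <- c(hrtf = 1L, neurons = 2L, reliability = 3L, gain = 4L,
               map = 5L, metrics = 6L, stats = 7L)
  (abs(seed) * 131L + offsets[[stage]] * 1009L) %% 2147480000L
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full pipeline
#'
#' Stages, in dependency order: synthesize HRIR sets per owl and condition;
#' reliability maps (per owl, then normalized cross-owl averages per
#' condition and the condition difference); gain maps; model-neuron
#' spatial maps; simulated neuron roster; tuning metrics; group statistics.
#' Identical config + seed give identical output hashes.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress to stderr.
#' @return Run manifest (named list of output files and their MD5 hashes),
#'   invisibly; also written to `<out_dir>/manifest.json`.
#' @export
run_all <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) {
    if (verbose) message("[owlcue] ", sprintf(...))
  }
  files <- character(0)

  # --- stage: synthetic heads -------------------------------------------
  log_stage("simulate-hrtf: %d owls x 2 conditions", config$n_owls)
  heads <- list()
  for (cond in c("normal", "ruff_removed")) {
    for (k in seq_len(config$n_owls)) {
      owl_seed <- stage_seed(config$seed, "hrtf") + k
      set <- make_head_model_hrirs(config$head, cond,
                                   azimuths_deg = config$azimuths_deg,
                                   owl_id = paste0("owl", k), seed = owl_seed)
      dir_k <- file.path(out, "hrtf", paste0("owl", k, "_", cond))
      write_hrir_set(set, dir_k)
      heads[[paste0(cond, k)]] <- set
      files <- c(files, file.path(dir_k, "manifest.json"))
    }
  }

  # --- stage: reliability -----------------------------------------------
  log_stage("reliability: %d repetitions, %d bands",
            config$reliability$n_repetitions,
            length(config$fb$center_freqs_hz))
  cfg_rel <- config$reliability
  cfg_rel$seed <- stage_seed(config$seed, "reliability")
  rel_rows <- list()
  cond_maps <- list()
  for (cond in c("normal", "ruff_removed")) {
    maps <- lapply(seq_len(config$n_owls), function(k) {
      reliability_map(heads[[paste0(cond, k)]], config$fb, cfg_rel)
    })
    for (k in seq_along(maps)) {
      d <- as.data.frame(normalize_reliability(maps[[k]]))
      d$owl_id <- paste0("owl", k)
      rel_rows[[paste0(cond, k)]] <- d
    }
    cond_maps[[cond]] <- normalize_and_average(maps)
  }
  rel_tsv <- write_tsv(do.call(rbind, rel_rows),
                       file.path(out, "reliability.tsv"))
  diff <- difference_map(cond_maps$normal, cond_maps$ruff_removed)
  diff_tsv <- write_tsv(as.data.frame(diff),
                        file.path(out, "reliability_difference.tsv"))
  files <- c(files, rel_tsv, diff_tsv)

  # --- stage: gain -------------------------------------------------------
  log_stage("gain: %d frequencies", length(config$gain_freqs_hz))
  gain_rows <- lapply(heads, function(h) {
    as.data.frame(gain_map(h, config$gain_freqs_hz))
  })
  gain_tsv <- write_tsv(do.call(rbind, gain_rows),
                        file.path(out, "gain.tsv"))
  files <- c(files, gain_tsv)

  # --- stage: model-neuron maps -----------------------------------------
  log_stage("neuron-map: tones %s Hz",
            paste(config$map_freqs_hz, collapse = ", "))
  map_rows <- list()
  for (cond in c("normal", "ruff_removed")) {
    h <- heads[[paste0(cond, 1L)]]
    for (f in config$map_freqs_hz) {
      p <- model_neuron_params(f = f)
      m <- as.data.frame(spatial_tuning_map(cue_field(h, f), p))
      m$condition <- cond
      map_rows[[paste(cond, f)]] <- m
    }
  }
  map_tsv <- write_tsv(do.call(rbind, map_rows),
                       file.path(out, "neuron_map.tsv"))
  files <- c(files, map_tsv)

  # --- stage: simulated neurons + metrics --------------------------------
  log_stage("simulate-neurons + tuning-metrics: %d neurons",
            length(config$roster))
  neuron_dir <- file.path(out, "neurons")
  dir.create(neuron_dir, showWarnings = FALSE)
  summaries <- list()
  for (i in seq_along(config$roster)) {
    gt <- config$roster[[i]]
    nseed <- stage_seed(config$seed, "neurons") + 10L * i
    itd_tab <- simulate_tuning_curves(gt, "itd_us", seed = nseed)
    frq_tab <- simulate_tuning_curves(gt, "freq_hz", seed = nseed + 1L)
    id <- sprintf("n%02d", i)
    write_trial_table(itd_tab, file.path(neuron_dir,
                                         paste0(id, "_itd.tsv")))
    write_trial_table(frq_tab, file.path(neuron_dir,
                                         paste0(id, "_freq.tsv")))
    files <- c(files, file.path(neuron_dir, paste0(id, "_itd.tsv")),
               file.path(neuron_dir, paste0(id, "_freq.tsv")))
    summaries[[i]] <- summarize_neuron(id, attr(gt, "group"),
                                       curve_from_trials(itd_tab),
                                       curve_from_trials(frq_tab))
  }
  summaries <- do.call(rbind, summaries)
  sum_tsv <- write_tsv(summaries, file.path(out, "summaries.tsv"))
  files <- c(files, sum_tsv)

  # --- stage: group statistics ------------------------------------------
  log_stage("group-stats")
  stats_out <- group_stats(summaries)
  stats_path <- file.path(out, "stats.json")
  jsonlite::write_json(stats_out, stats_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  files <- c(files, stats_path)

  manifest <- list(seed = config$seed,
                   files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("done: %d output files", length(files))
  invisible(manifest)
}
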