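# IPD reliability across frequency and target azimuth under concurrent-
# sound corruption. For each repetition a fresh target and masker token are
# drawn; for every (target azimuth, masker azimuth) pair both are rendered
# through the head, summed, decomposed by the gammatone filterbank, and the
# per-band IPD extracted from the cross-correlation peak. Reliability at a
# (target azimuth, band) cell is the inverse of the circular standard
# deviation of IPD across masker locations (averaged across repetitions):
# a band whose phase survives corruption from anywhere is reliable.
#
# Engine note: per (target, masker) pair the left/right sum signals are
# formed in the frequency domain, their broadband cross-spectrum X is
# computed once, and each band's cross-correlation is recovered as
# ifft(X * |G_b|^2) — one inverse FFT per band (mvfft over all bands)
# instead of filtering and correlating per band in the time domain.

#' Configuration of the reliability computation
#'
#' @param masker_amplitude Masker scaling as a fraction of target
#'   *amplitude* (not power). Default 1.0; the standard alternate condition
#'   is 0.5.
#' @param n_repetitions Fresh target/masker token draws (default 10).
#' @param stimulus `"broadband"` (flat-spectrum 0.5-10 kHz noise) or
#'   `"vocalization_surrogate"`.
#' @param duration_s Token duration in seconds (default 0.1).
#' @param include_coincident_masker Include the masker placed at the target
#'   azimuth itself (default TRUE).
#' @param epsilon_sd Floor (radians) applied to the mean circular SD before
#'   inversion, so reliability stays finite when corruption vanishes.
#' @param seed Integer seed; tokens depend only on (seed, repetition), so
#'   runs on different owls/conditions with the same config are paired.
#' @return List of class `reliability_config`.
#' @export
reliability_config <- function(masker_amplitude = 1.0,
                               n_repetitions = 10L,
                               stimulus = c("broadband",
                                            "vocalization_surrogate"),
                               duration_s = 0.1,
                               include_coincident_masker = TRUE,
                               epsilon_sd = 1e-3,
                               seed = 0L) {
  stimulus <- match.arg(stimulus)
  stopifnot(masker_amplitude >= 0, n_repetitions >= 1L, duration_s > 0,
            epsilon_sd > 0)
  structure(list(masker_amplitude = masker_amplitude,
                 n_repetitions = as.integer(n_repetitions),
                 stimulus = stimulus, duration_s = duration_s,
                 include_coincident_masker = include_coincident_masker,
                 epsilon_sd = epsilon_sd, seed = as.integer(seed)),
            class = "reliability_config")
}

reliability_stimulus <- function(cfg, fs, seed) {
  if (cfg$stimulus == "broadband") {
    make_broadband_stimulus(500, min(10000, fs / 2 - 100), cfg$duration_s,
                            fs, seed = seed)
  } else {
    make_vocalization_surrogate(cfg$duration_s, fs, seed = seed)
  }
}

# circular SD column-wise over a matrix of angles (rows = observations);
# NA angles dropped per column; columns with < 2 finite angles give NA.
# Unbounded dispersion is capped at sd_cap so reliability stays positive.
circular_sd_cols <- function(theta, sd_cap = sqrt(-2 * log(1e-8))) {
  z <- exp(1i * theta)
  n_ok <- colSums(is.finite(theta))
  z[!is.finite(theta)] <- 0
  rbar <- Mod(colSums(z)) / pmax(n_ok, 1L)
  sd <- sqrt(-2 * log(pmax(pmin(rbar, 1), 1e-8)))
  sd[n_ok < 2L] <- NA_real_
  pmin(sd, sd_cap)
}

#' IPD reliability map of a single HRIR set
#'
#' @param set An [hrir_set()] covering an elevation-0 azimuth scan (other
#'   elevations are ignored).
#' @param fb A [filterbank_spec()].
#' @param cfg A [reliability_config()].
#' @return Object of class `reliability_map` with fields `frequencies_hz`,
#'   `target_azimuths_deg`, `sd_rad` (mean circular SD, frequency x
#'   azimuth), `raw` (its inverse, rad^-1), `normalized` (`NULL` until
#'   [normalize_reliability()]), and `provenance`.
#' @export
reliability_map <- function(set, fb = filterbank_spec(),
                            cfg = reliability_config()) {
  stopifnot(inherits(set, "hrir_set"), inherits(fb, "filterbank_spec"),
            inherits(cfg, "reliability_config"))
  set <- horizontal_slice(set)
  fs <- set$sample_rate_hz
  if (max(fb$center_freqs_hz) >= fs / 2) {
    stop("filterbank centres must be below Nyquist", call. = FALSE)
  }
  az <- set$directions$azimuth_deg
  n_az <- length(az)
  if (n_az < 2L) stop("need >= 2 azimuths for masker corruption",
                      call. = FALSE)
  fcs <- fb$center_freqs_hz
  n_b <- length(fcs)
  n_sig <- round(cfg$duration_s * fs)
  hl <- hrir_length(set)
  max_lag <- round(1e-3 * fs)
  g_irs <- lapply(fcs, gammatone_ir, fs_hz = fs, order = fb$order,
                  bw_scale = fb$bw_scale)
  n_fft <- next_pow2(n_sig + hl + max(lengths(g_irs)) + 2L * max_lag)

  # band power responses |G_b|^2 on the common FFT grid
  W <- vapply(g_irs, function(g) {
    Mod(stats::fft(c(g, numeric(n_fft - length(g)))))^2
  }, numeric(n_fft))
  H_L <- vapply(set$left, function(h) {
    stats::fft(c(h, numeric(n_fft - hl)))
  }, complex(n_fft))
  H_R <- vapply(set$right, function(h) {
    stats::fft(c(h, numeric(n_fft - hl)))
  }, complex(n_fft))

  lag_idx <- c(n_fft - (max_lag:1) + 1L, seq_len(max_lag + 1L))
  lag_val <- (-max_lag:max_lag) / fs               # seconds, ordered
  two_pi_f <- 2 * pi * fcs

  sd_sum <- matrix(0, n_b, n_az)
  sd_n <- matrix(0L, n_b, n_az)
  for (rep_i in seq_len(cfg$n_repetitions)) {
    target <- reliability_stimulus(cfg, fs,
                                   seed = cfg$seed + 2L * rep_i - 1L)
    masker <- reliability_stimulus(cfg, fs, seed = cfg$seed + 2L * rep_i)
    S_t <- stats::fft(c(target, numeric(n_fft - n_sig)))
    S_m <- stats::fft(c(masker, numeric(n_fft - n_sig))) *
      cfg$masker_amplitude
    T_L <- H_L * S_t; T_R <- H_R * S_t
    M_L <- H_L * S_m; M_R <- H_R * S_m
    for (i in seq_len(n_az)) {
      maskers <- if (cfg$include_coincident_masker) seq_len(n_az)
                 else setdiff(seq_len(n_az), i)
      ipd <- matrix(NA_real_, length(maskers), n_b)
      for (jj in seq_along(maskers)) {
        j <- maskers[jj]
        s_l <- T_L[, i] + M_L[, j]
        s_r <- T_R[, i] + M_R[, j]
        X <- s_l * Conj(s_r)
        R <- Re(stats::mvfft(X * W, inverse = TRUE))[lag_idx, , drop = FALSE]
        best <- max.col(t(R), ties.method = "first")
        # parabolic sub-sample refinement of each band's peak lag
        n_lag <- length(lag_val)
        interior <- best > 1L & best < n_lag
        cols <- seq_len(n_b)
        y0 <- R[cbind(best, cols)]
        frac <- numeric(n_b)
        if (any(interior)) {
          bi <- best[interior]; ci <- cols[interior]
          ym <- R[cbind(bi - 1L, ci)]
          yp <- R[cbind(bi + 1L, ci)]
          denom <- ym - 2 * y0[interior] + yp
          d <- ifelse(denom < 0, 0.5 * (ym - yp) / denom, 0)
          frac[interior] <- pmax(pmin(d, 0.5), -0.5)
        }
        tau <- lag_val[best] + frac / fs
        # flag zero-energy bands (target+masker cancel or out of band)
        e_l <- crossprod(W, Mod(s_l)^2)
        e_r <- crossprod(W, Mod(s_r)^2)
        ok <- (e_l > 1e-12) & (e_r > 1e-12)
        phi <- wrap_angle(two_pi_f * tau)
        phi[!ok] <- NA_real_
        ipd[jj, ] <- phi
      }
      sds <- circular_sd_cols(ipd)
      has <- is.finite(sds)
      sd_sum[, i][has] <- sd_sum[, i][has] + sds[has]
      sd_n[, i][has] <- sd_n[, i][has] + 1L
    }
  }
  sd_mean <- sd_sum / pmax(sd_n, 1L)
  sd_mean[sd_n == 0L] <- NA_real_
  raw <- 1 / pmax(sd_mean, cfg$epsilon_sd)
  dimnames(raw) <- dimnames(sd_mean) <-
    list(frequency_hz = fcs, azimuth_deg = az)
  structure(list(frequencies_hz = fcs, target_azimuths_deg = az,
                 sd_rad = sd_mean, raw = raw, normalized = NULL,
                 provenance = list(owl_ids = set$owl_id,
                                   condition = set$condition,
                                   config = unclass(cfg),
                                   filterbank = unclass(fb))),
            class = "reliability_map")
}

#' @export
print.reliability_map <- function(x, ...) {
  cat(sprintf("<reliability_map> %d bands x %d azimuths (%s)\n",
              length(x$frequencies_hz), length(x$target_azimuths_deg),
              paste(x$provenance$condition, collapse = ",")))
  cat(sprintf("  owls: %s; normalized: %s\n",
              paste(x$provenance$owl_ids, collapse = ", "),
              if (is.null(x$normalized)) "no" else "yes"))
  invisible(x)
}

#' Normalize a reliability map per target azimuth
#'
#' Each azimuth column is divided by its own maximum across frequencies,
#' so every location's most reliable band scores 1.
#'
#' @param map A `reliability_map`.
#' @return The map with its `normalized` field filled.
#' @export
normalize_reliability <- function(map) {
  stopifnot(inherits(map, "reliability_map"))
  col_max <- apply(map$raw, 2L, max, na.rm = TRUE)
  map$normalized <- sweep(map$raw, 2L, col_max, "/")
  map
}

check_same_grid <- function(a, b) {
  if (!isTRUE(all.equal(a$frequencies_hz, b$frequencies_hz)) ||
      !isTRUE(all.equal(a$target_azimuths_deg, b$target_azimuths_deg))) {
    stop("reliability maps are on different grids", call. = FALSE)
  }
}

#' Normalize per owl, then average across owls
#'
#' Each owl's map is normalized per target azimuth ([normalize_reliability()])
#' and the normalized maps are then averaged cell-wise. Normalization before
#' averaging keeps owls with different absolute reliability from dominating.
#'
#' @param maps List of single-owl `reliability_map`s on the same grid.
#' @param normalize_first If `FALSE`, raw maps are averaged across owls
#'   first and the average is then normalized (non-default alternative).
#' @return A `reliability_map` whose `normalized` field is the across-owl
#'   average (and `raw` the mean of raw maps).
#' @export
normalize_and_average <- function(maps, normalize_first = TRUE) {
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, inherits, TRUE, "reliability_map")))
  for (m in maps[-1L]) check_same_grid(maps[[1L]], m)
  raw_mean <- Reduce(`+`, lapply(maps, `[[`, "raw")) / length(maps)
  if (normalize_first) {
    normed <- lapply(maps, function(m) normalize_reliability(m)$normalized)
    avg <- Reduce(`+`, normed) / length(maps)
  } else {
    cm <- apply(raw_mean, 2L, max, na.rm = TRUE)
    avg <- sweep(raw_mean, 2L, cm, "/")
  }
  out <- maps[[1L]]
  out$raw <- raw_mean
  out$sd_rad <- Reduce(`+`, lapply(maps, `[[`, "sd_rad")) / length(maps)
  out$normalized <- avg
  out$provenance$owl_ids <-
    unlist(lapply(maps, function(m) m$provenance$owl_ids))
  out$provenance$condition <-
    unique(unlist(lapply(maps, function(m) m$provenance$condition)))
  out
}

#' Signed difference of two normalized reliability maps
#'
#' @param a,b Normalized `reliability_map`s on the same grid (typically
#'   ruff-intact minus ruff-removed).
#' @return A `reliability_map` whose `normalized` field holds `a - b`
#'   cell-wise (values may be negative); `raw`/`sd_rad` are dropped.
#' @export
difference_map <- function(a, b) {
  stopifnot(inherits(a, "reliability_map"), inherits(b, "reliability_map"))
  check_same_grid(a, b)
  if (is.null(a$normalized) || is.null(b$normalized)) {
    stop("difference_map needs normalized maps (see normalize_reliability)",
         call. = FALSE)
  }
  out <- a
  out$normalized <- a$normalized - b$normalized
  out$raw <- NULL
  out$sd_rad <- NULL
  out$provenance <- list(
    owl_ids = union(a$provenance$owl_ids, b$provenance$owl_ids),
    condition = paste(a$provenance$condition[1L], "-",
                      b$provenance$condition[1L]),
    config = a$provenance$config)
  out
}

#' Long-format data frame of a reliability map
#'
#' @param x A `reliability_map`.
#' @param ... Unused.
#' @return Data frame with one row per (frequency, azimuth) cell.
#' @export
as.data.frame.reliability_map <- function(x, ...) {
  grid <- expand.grid(freq_hz = x$frequencies_hz,
                      target_az_deg = x$target_azimuths_deg,
                      KEEP.OUT.ATTRS = FALSE)
  grid$owl_id <- paste(x$provenance$owl_ids, collapse = ",")
  grid$condition <- paste(x$provenance$condition, collapse = ",")
  if (!is.null(x$sd_rad)) grid$raw_sd_rad <- as.vector(x$sd_rad)
  if (!is.null(x$raw)) grid$reliability_raw <- as.vector(x$raw)
  if (!is.null(x$normalized)) {
    grid$reliability_norm <- as.vector(x$normalized)
  }
  grid
}
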