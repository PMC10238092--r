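#' Binaural head-related impulse response (HRIR) set
#'
#' An `hrir_set` holds one owl/condition's binaural impulse responses on a
#' grid of source directions. It is the package's canonical container: the
#' reliability, gain and model-neuron pipelines all consume it.
#'
#' Sign conventions used package-wide: positive azimuth = source to the
#' *right* of the midline; positive elevation = up; positive ITD = sound
#' arrives at the right ear first (t_left - t_right > 0); ILD is reported as
#' right minus left in dB.
#'
#' @param owl_id Character label identifying the individual.
#' @param condition One of `"normal"`, `"ruff_removed"`, `"synthetic_custom"`.
#' @param sample_rate_hz Sampling rate in Hz. Must be at least 20 kHz so
#'   the 1-10 kHz analysis range is below Nyquist.
#' @param directions Data frame with numeric columns `azimuth_deg`
#'   (within \[-180, 180\]) and `elevation_deg` (within \[-90, 90\]).
#' @param left,right Lists of numeric vectors, one impulse response per
#'   direction; all the same length, all finite.
#'
#' @return An object of class `hrir_set`.
#' @export
hrir_set <- function(owl_id, condition, sample_rate_hz, directions,
                     left, right) {
  condition <- match.arg(condition,
                         c("normal", "ruff_removed", "synthetic_custom"))
  stopifnot(is.character(owl_id), length(owl_id) == 1L)
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz < 20000) {
    stop("sample_rate_hz must be a single number >= 20000 Hz", call. = FALSE)
  }
  directions <- as.data.frame(directions)
  if (!all(c("azimuth_deg", "elevation_deg") %in% names(directions))) {
    stop("directions needs columns azimuth_deg and elevation_deg",
         call. = FALSE)
  }
  n <- nrow(directions)
  if (n < 1L) stop("at least one direction is required", call. = FALSE)
  az <- directions$azimuth_deg
  el <- directions$elevation_deg
  if (any(!is.finite(az)) || any(az < -180 | az > 180)) {
    stop("azimuth_deg must be finite and within [-180, 180]", call. = FALSE)
  }
  if (any(!is.finite(el)) || any(el < -90 | el > 90)) {
    stop("elevation_deg must be finite and within [-90, 90]", call. = FALSE)
  }
  # duplicate directions compared at 1e-6 degree tolerance
  key <- paste(round(az / 1e-6), round(el / 1e-6))
  if (anyDuplicated(key)) {
    stop("duplicate directions in HRIR set (tolerance 1e-6 degrees)",
         call. = FALSE)
  }
  if (!is.list(left) || !is.list(right) ||
      length(left) != n || length(right) != n) {
    stop("left and right must be lists with one impulse response per direction",
         call. = FALSE)
  }
  lens <- c(vapply(left, length, 1L), vapply(right, length, 1L))
  if (length(unique(lens)) != 1L) {
    stop("all impulse responses must have the same length", call. = FALSE)
  }
  ok <- vapply(c(left, right), function(h) all(is.finite(h)), TRUE)
  if (!all(ok)) stop("impulse responses must be finite", call. = FALSE)

  structure(
    list(owl_id = owl_id, condition = condition,
         sample_rate_hz = as.numeric(sample_rate_hz),
         directions = directions[, c("azimuth_deg", "elevation_deg")],
         left = left, right = right),
    class = "hrir_set")
}

#' @export
print.hrir_set <- function(x, ...) {
  cat(sprintf("<hrir_set> owl '%s', condition '%s'\n", x$owl_id, x$condition))
  cat(sprintf("  %d directions, %d taps @ %g Hz\n",
              nrow(x$directions), length(x$left[[1L]]), x$sample_rate_hz))
  cat(sprintf("  azimuth %g..%g deg, elevation %g..%g deg\n",
              min(x$directions$azimuth_deg), max(x$directions$azimuth_deg),
              min(x$directions$elevation_deg), max(x$directions$elevation_deg)))
  invisible(x)
}

#' Number of taps in each impulse response of an HRIR set
#' @param set An `hrir_set`.
#' @return Integer tap count.
#' @export
hrir_length <- function(set) length(set$left[[1L]])

#' Locate a direction in an HRIR set
#'
#' @param set An `hrir_set`.
#' @param azimuth_deg,elevation_deg Direction to find.
#' @param tol Matching tolerance in degrees.
#' @return Row index into `set$directions`, or `NA_integer_` if absent.
#' @export
direction_index <- function(set, azimuth_deg, elevation_deg = 0, tol = 1e-6) {
  i <- which(abs(set$directions$azimuth_deg - azimuth_deg) <= tol &
             abs(set$directions$elevation_deg - elevation_deg) <= tol)
  if (length(i) == 0L) NA_integer_ else i[1L]
}

#' Validate an HRIR set against a required direction grid
#'
#' Report-only check that the set covers a requested grid (the standard
#' measurement grid is azimuth -160..160 deg in 20 deg steps at elevation 0).
#' Extra directions beyond the grid do not make the set incomplete.
#'
#' @param set An `hrir_set`.
#' @param azimuths_deg,elevations_deg Numeric vectors defining the required
#'   grid (their Cartesian product).
#' @param tol Matching tolerance in degrees.
#' @return A list with `complete` (logical), `missing` and `extra`
#'   (data frames of directions).
#' @export
validate_grid <- function(set,
                          azimuths_deg = seq(-160, 160, by = 20),
                          elevations_deg = 0,
                          tol = 1e-6) {
  req <- expand.grid(azimuth_deg = azimuths_deg,
                     elevation_deg = elevations_deg,
                     KEEP.OUT.ATTRS = FALSE)
  have <- set$directions
  match_dir <- function(a, e, tab) {
    any(abs(tab$azimuth_deg - a) <= tol & abs(tab$elevation_deg - e) <= tol)
  }
  miss <- !mapply(match_dir, req$azimuth_deg, req$elevation_deg,
                  MoreArgs = list(tab = have))
  extra <- !mapply(match_dir, have$azimuth_deg, have$elevation_deg,
                   MoreArgs = list(tab = req))
  list(complete = !any(miss),
       missing = req[miss, , drop = FALSE],
       extra = have[extra, , drop = FALSE])
}

#' Restrict an HRIR set to its elevation-0 azimuth scan
#'
#' @param set An `hrir_set`.
#' @param tol Elevation tolerance in degrees.
#' @return An `hrir_set` containing only elevation-0 directions, sorted by
#'   azimuth.
#' @export
horizontal_slice <- function(set, tol = 1e-6) {
  keep <- which(abs(set$directions$elevation_deg) <= tol)
  if (length(keep) == 0L) {
    stop("HRIR set has no elevation-0 directions", call. = FALSE)
  }
  keep <- keep[order(set$directions$azimuth_deg[keep])]
  hrir_set(set$owl_id, set$condition, set$sample_rate_hz,
           set$directions[keep, , drop = FALSE],
           set$left[keep], set$right[keep])
}
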