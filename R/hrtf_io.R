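# Canonical on-disk dialect for HRIR sets: a JSON manifest plus one stereo
# float-32 WAV file per direction (channel 1 = left ear, channel 2 = right).
# Simple, diffable and language-neutral. A read-only SOFA loader for the
# SimpleFreeFieldHRIR convention is provided separately (read_sofa_hrir).

#' Write an HRIR set to a manifest directory
#'
#' Lays out `manifest.json` plus one two-channel 32-bit-float WAV per
#' direction, readable back with [read_hrir_set()]. Lossless at float32
#' precision.
#'
#' @param set An [hrir_set()].
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_hrir_set <- function(set, path) {
  stopifnot(inherits(set, "hrir_set"))
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE,
                                       showWarnings = FALSE)
  if (!ok) stop("cannot create directory '", path, "'", call. = FALSE)
  n <- nrow(set$directions)
  files <- sprintf("dir_%03d.wav", seq_len(n) - 1L)
  for (i in seq_len(n)) {
    write_wav_float(file.path(path, files[i]),
                    cbind(set$left[[i]], set$right[[i]]),
                    set$sample_rate_hz)
  }
  manifest <- list(
    owl_id = set$owl_id,
    condition = set$condition,
    sample_rate_hz = set$sample_rate_hz,
    directions = data.frame(
      azimuth_deg = set$directions$azimuth_deg,
      elevation_deg = set$directions$elevation_deg,
      file = files))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an HRIR set
#'
#' Reads either the package's manifest dialect (a directory containing
#' `manifest.json` and per-direction stereo WAV files) or, if `path` is a
#' single file, a SOFA SimpleFreeFieldHRIR container via [read_sofa_hrir()].
#'
#' @param path Manifest directory (or the manifest.json itself), or a SOFA
#'   file.
#' @return An [hrir_set()]; direction order preserved from the manifest.
#' @export
read_hrir_set <- function(path) {
  if (file.exists(path) && !dir.exists(path) &&
      !grepl("manifest\\.json$", path)) {
    return(read_sofa_hrir(path))
  }
  manifest_path <- if (dir.exists(path)) file.path(path, "manifest.json")
                   else path
  root <- dirname(manifest_path)
  if (!file.exists(manifest_path)) {
    stop("manifest not found: '", manifest_path, "'", call. = FALSE)
  }
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dirs <- as.data.frame(m$directions)
  # JSON round-trips whole numbers as integers; the container is double
  dirs$azimuth_deg <- as.numeric(dirs$azimuth_deg)
  dirs$elevation_deg <- as.numeric(dirs$elevation_deg)
  n <- nrow(dirs)
  left <- vector("list", n)
  right <- vector("list", n)
  for (i in seq_len(n)) {
    f <- file.path(root, dirs$file[i])
    if (!file.exists(f)) {
      stop("HRIR audio file missing: '", f, "'", call. = FALSE)
    }
    wav <- read_wav_float(f)
    if (wav$sample_rate_hz != m$sample_rate_hz) {
      stop("sample-rate mismatch in '", f, "': manifest says ",
           m$sample_rate_hz, " Hz, file says ", wav$sample_rate_hz, " Hz",
           call. = FALSE)
    }
    if (ncol(wav$samples) != 2L) {
      stop("'", f, "' must be a 2-channel WAV (left, right)", call. = FALSE)
    }
    left[[i]] <- wav$samples[, 1L]
    right[[i]] <- wav$samples[, 2L]
  }
  hrir_set(m$owl_id, m$condition, m$sample_rate_hz,
           dirs[, c("azimuth_deg", "elevation_deg")], left, right)
}

#' Read a SOFA SimpleFreeFieldHRIR file
#'
#' Optional reader for the AES69 "SOFA" container used by public HRTF
#' repositories. SOFA files are netCDF-4/HDF5; since no HDF5 reader is
#' available in this R stack, the file is decoded by a small bundled Python
#' helper (h5py) and handed back as JSON. SOFA's spherical coordinate
#' convention measures azimuth counterclockwise (left of midline positive);
#' azimuths are negated on import to match the package convention
#' (right positive). Receiver 1 is taken as the left ear.
#'
#' @param path Path to a `.sofa` file.
#' @param owl_id,condition Metadata to attach (SOFA files do not carry the
#'   experiment's condition labels).
#' @param python Python interpreter to use.
#' @return An [hrir_set()].
#' @export
read_sofa_hrir <- function(path, owl_id = "sofa", condition = "normal",
                           python = Sys.which("python")) {
  if (!file.exists(path)) stop("SOFA file not found: '", path, "'",
                               call. = FALSE)
  if (!nzchar(python)) {
    stop("reading SOFA requires a python interpreter with h5py",
         call. = FALSE)
  }
  helper <- system.file("python", "sofa_to_json.py", package = "owlcue")
  out <- tempfile(fileext = ".json")
  on.exit(unlink(out))
  status <- system2(python, c(shQuote(helper), shQuote(path), shQuote(out)),
                    stdout = FALSE, stderr = "")
  if (status != 0L || !file.exists(out)) {
    stop("failed to decode SOFA file '", path, "'", call. = FALSE)
  }
  d <- jsonlite::read_json(out, simplifyVector = TRUE)
  # d$ir is [measurement x receiver x sample]
  n <- length(d$azimuth_deg)
  az <- -d$azimuth_deg                       # SOFA ccw -> package cw
  az <- ((az + 180) %% 360) - 180
  az[az == -180] <- 180
  left <- lapply(seq_len(n), function(i) as.numeric(d$ir[i, 1L, ]))
  right <- lapply(seq_len(n), function(i) as.numeric(d$ir[i, 2L, ]))
  hrir_set(owl_id, condition, d$sample_rate_hz,
           data.frame(azimuth_deg = az, elevation_deg = d$elevation_deg),
           left, right)
}
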