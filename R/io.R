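RECORDING_SCHEMA <- 1L
RESULTS_SCHEMA <- 1L

recording_units <- list(
  abp = c(time_s = "s", abp_mmhg = "mmHg"),
  nirs = "uM*mm",
  vitals = c(time_s = "s", hr_bpm = "bpm", spo2_pct = "%",
             etco2_kpa = "kPa", map_mmhg = "mmHg")
)

# write a data frame as CSV with round-trip-exact doubles (%.17g)
write_csv_exact <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.double),
    function(x) sub("^(-?\\d+)$", "\\1", sprintf("%.17g", x))
  ))
  readr::write_csv(df, path)
}

#' Write a recording bundle to disk
#'
#' Serializes a `nirs_recording` as a directory of RFC-4180 CSV files (ABP
#' waveform, NIRS channels, channel metadata, vitals, events) plus a JSON
#' manifest holding the schema version, subject id, ISO-8601 clock origin,
#' sampling rates, per-column units, and an MD5 checksum of every file.
#' Units are carried in the column names (`time_s`, `abp_mmhg`, ...) and in
#' the manifest. Ground-truth elements of synthetic recordings are not
#' written.
#'
#' @param recording A `nirs_recording`.
#' @param path Directory to create/populate.
#' @param subject_id Identifier recorded in the manifest.
#' @param clock_origin ISO-8601 timestamp of time zero.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, subject_id = "synthetic",
                            clock_origin = "1970-01-01T00:00:00Z") {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- list(abp = "abp.csv", nirs = "nirs.csv", channels = "channels.csv",
                vitals = "vitals.csv", events = "events.csv")
  write_csv_exact(recording$abp, file.path(path, files$abp))
  write_csv_exact(recording$nirs, file.path(path, files$nirs))
  readr::write_csv(recording$channels, file.path(path, files$channels))
  write_csv_exact(recording$vitals, file.path(path, files$vitals))
  readr::write_csv(recording$events, file.path(path, files$events))

  sums <- vapply(files, function(f) {
    unname(tools::md5sum(file.path(path, f)))
  }, character(1))
  manifest <- list(
    schema_version = RECORDING_SCHEMA,
    subject_id = subject_id,
    clock_origin = clock_origin,
    fs_raw = recording$fs_raw,
    vitals_fs = recording$vitals_fs,
    units = recording_units,
    files = as.list(sums)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a recording bundle from disk
#'
#' Validates the manifest (schema version, file presence, MD5 checksums)
#' and reconstructs a `nirs_recording`. Errors name the offending file.
#'
#' @param path Directory written by [write_recording()].
#' @return A `nirs_recording` (without generator ground truth).
#' @export
read_recording <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) abort(paste0("Missing manifest: ", mf_path))
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (manifest$schema_version > RECORDING_SCHEMA) {
    abort(paste0("Recording schema version ", manifest$schema_version,
                 " is newer than supported version ", RECORDING_SCHEMA, "."))
  }
  for (f in names(manifest$files)) {
    fp <- file.path(path, paste0(f, ".csv"))
    if (!file.exists(fp)) abort(paste0("Missing recording file: ", fp))
    if (unname(tools::md5sum(fp)) != manifest$files[[f]]) {
      abort(paste0("Checksum mismatch for ", fp))
    }
  }
  # base-R read.csv parses decimal literals exactly (strtod), which keeps
  # the write -> read round trip bit-identical for doubles
  rd <- function(f) {
    as_tibble(utils::read.csv(file.path(path, paste0(f, ".csv"))))
  }
  abp <- rd("abp")
  nirs <- rd("nirs")
  channels <- rd("channels")
  vitals <- rd("vitals")
  events <- rd("events")
  structure(
    list(abp = abp, nirs = nirs, channels = channels, vitals = vitals,
         events = events, fs_raw = manifest$fs_raw,
         vitals_fs = manifest$vitals_fs,
         config = NULL, truth = NULL,
         subject_id = manifest$subject_id,
         clock_origin = manifest$clock_origin),
    class = "nirs_recording"
  )
}

#' Write pipeline results to disk
#'
#' Writes the per-segment, per-channel, per-band TFA rows as CSV
#' (deterministic column order) and, optionally, fitted mixed-model
#' summaries as JSON (tidy coefficients, glance summary, formula). A small
#' results manifest records the schema version.
#'
#' @param tfa_results Tibble from [run_pipeline()] (possibly empty).
#' @param path Output directory.
#' @param fits Optional named list of `phase_lmm` objects.
#' @return `path`, invisibly.
#' @export
write_results <- function(tfa_results, path, fits = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tfa_results, file.path(path, "tfa_results.csv"))
  payload <- list(schema_version = RESULTS_SCHEMA)
  if (!is.null(fits)) {
    payload$fits <- purrr::map(fits, function(f) {
      list(formula = deparse(f$formula), coefficients = tidy(f),
           summary = glance(f))
    })
  }
  jsonlite::write_json(payload, file.path(path, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' Read pipeline results from disk
#'
#' @param path Directory written by [write_results()].
#' @return List with `tfa` (tibble) and `fits` (list, possibly empty).
#' @export
read_results <- function(path) {
  fj <- jsonlite::read_json(file.path(path, "fits.json"),
                            simplifyVector = TRUE)
  if (fj$schema_version > RESULTS_SCHEMA) {
    abort(paste0("Results schema version ", fj$schema_version,
                 " is newer than supported version ", RESULTS_SCHEMA, "."))
  }
  tfa <- readr::read_csv(file.path(path, "tfa_results.csv"),
                         col_types = readr::cols())
  list(tfa = tfa, fits = fj$fits %||% list())
}

#' Read optical-density series from a SNIRF file
#'
#' Minimal SNIRF (HDF5) ingestion for two-wavelength continuous-wave data:
#' reads `/nirs/data1/dataTimeSeries`, the per-column measurement lists,
#' probe wavelengths, and source/detector positions; groups columns into
#' source-detector channels; derives the source-detector separation and the
#' channel role (>= 20 mm long, otherwise short). Requires the `rhdf5`
#' package.
#'
#' @param path Path to a `.snirf` file.
#' @return List with `channels` (tibble: `channel`, `separation_mm`,
#'   `role`) and `od` (named list of tibbles `time_s`, `od1`, `od2`, with a
#'   `wavelengths_nm` attribute).
#' @export
read_snirf <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    abort("Package `rhdf5` is required to read SNIRF files.")
  }
  nirs <- rhdf5::h5read(path, "/nirs")
  dat <- nirs$data1
  ts <- dat$dataTimeSeries
  time <- as.numeric(dat$time)
  if (is.null(dim(ts))) ts <- matrix(ts, ncol = 1)
  # SNIRF stores time x measurement; transpose if needed
  if (nrow(ts) != length(time) && ncol(ts) == length(time)) ts <- t(ts)
  wl <- as.numeric(nirs$probe$wavelengths)
  if (length(wl) != 2) abort("Exactly two wavelengths are supported.")
  spos <- nirs$probe$sourcePos3D %||% nirs$probe$sourcePos2D
  dpos <- nirs$probe$detectorPos3D %||% nirs$probe$detectorPos2D
  if (is.null(dim(spos))) spos <- matrix(spos, nrow = 1)
  if (is.null(dim(dpos))) dpos <- matrix(dpos, nrow = 1)
  if (ncol(spos) > 3) spos <- t(spos)
  if (ncol(dpos) > 3) dpos <- t(dpos)

  ml_names <- grep("^measurementList", names(dat), value = TRUE)
  ml_names <- ml_names[order(as.integer(sub("measurementList", "", ml_names)))]
  ml <- purrr::map_dfr(ml_names, function(nm) {
    m <- dat[[nm]]
    tibble(source = as.integer(m$sourceIndex),
           detector = as.integer(m$detectorIndex),
           wavelength = as.integer(m$wavelengthIndex))
  })
  ml$col <- seq_len(nrow(ml))

  pairs <- dplyr::distinct(ml, .data$source, .data$detector)
  od <- list()
  meta <- list()
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$source[i]
    d <- pairs$detector[i]
    cols <- ml[ml$source == s & ml$detector == d, ]
    cols <- cols[order(cols$wavelength), ]
    if (nrow(cols) != 2) abort("Each channel must have exactly two wavelengths.")
    sep <- sqrt(sum((spos[s, ] - dpos[d, ])^2))
    name <- paste0("S", s, "D", d)
    series <- tibble(time_s = time,
                     od1 = as.numeric(ts[, cols$col[1]]),
                     od2 = as.numeric(ts[, cols$col[2]]))
    attr(series, "wavelengths_nm") <- wl
    od[[name]] <- series
    meta[[i]] <- tibble(channel = name, separation_mm = sep,
                        role = if (sep >= 20) "long" else "short")
  }
  list(channels = dplyr::bind_rows(meta), od = od)
}
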