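#' Construct an sEMG recording object
#'
#' Bundles a multi-channel sEMG matrix, the knee-angle goniometer trace and
#' the per-recording metadata used throughout the pipeline.
#'
#' @param semg Numeric matrix, channels x samples (mV scale, raw).
#' @param angle Numeric vector of knee angles in degrees, one per sample.
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier string.
#' @param group `"CG"` (control) or `"SG"` (knee pathology).
#' @param motion `"STD"` (standing leg flexion), `"ST"` (sitting leg
#'   extension) or `"Gait"` (level walking).
#' @param channel_names Muscle labels, one per sEMG channel.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(semg, angle, fs, subject_id, group, motion,
                          channel_names = rownames(semg)) {
  semg <- as.matrix(semg)
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(semg)))
  }
  if (ncol(semg) != length(angle)) {
    stop("semg and angle must have the same number of samples (",
         ncol(semg), " vs ", length(angle), ")")
  }
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive sampling rate")
  if (length(channel_names) != nrow(semg)) {
    stop("channel_names must have one entry per sEMG channel")
  }
  group <- match.arg(group, c("CG", "SG"))
  motion <- match.arg(motion, c("STD", "ST", "Gait"))
  rownames(semg) <- channel_names
  structure(
    list(semg = semg, angle = as.numeric(angle), fs = fs,
         subject_id = as.character(subject_id), group = group,
         motion = motion, channel_names = channel_names),
    class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> subject %s (%s), motion %s: %d channels x %d samples @ %g Hz\n",
    x$subject_id, x$group, x$motion, nrow(x$semg), ncol(x$semg), x$fs))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Read a delimited-text sEMG recording
#'
#' Reads one recording stored as columnar text (tab- or comma-delimited,
#' auto-detected, with an optional single header line). The `layout` maps
#' named sEMG channels and the goniometer trace to 0-based column indices.
#'
#' @param path Path to the delimited text file.
#' @param layout Named integer vector of 0-based column indices; must
#'   contain an `angle` entry, all other entries are sEMG channel names,
#'   e.g. `c(RF = 0, FB = 1, VM = 2, SEM = 3, angle = 4)`.
#' @param subject_id,group,motion Recording metadata (see
#'   [emg_recording()]).
#' @param fs Sampling rate in Hz (the source dataset records at 1000 Hz).
#' @return An [emg_recording()] object.
#' @export
read_recording <- function(path, layout, subject_id, group, motion,
                           fs = 1000) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(names(layout)) || !"angle" %in% names(layout)) {
    stop("configuration error: layout must name an 'angle' column")
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(fields)))
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           skip = if (has_header) 1L else 0L,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  need <- as.integer(layout) + 1L
  missing_cols <- names(layout)[need > ncol(tab) | need < 1L]
  if (length(missing_cols)) {
    stop("configuration error: column(s) not present in file: ",
         paste(missing_cols, collapse = ", "))
  }
  parse_col <- function(name) {
    raw <- tab[[need[match(name, names(layout))]]]
    vals <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(vals) & !(trimws(raw) %in% c("NA", "")))
    if (length(bad)) {
      stop("parse error: non-numeric value '", raw[bad[1]],
           "' in column '", name, "' at line ",
           bad[1] + if (has_header) 1L else 0L)
    }
    vals
  }
  ch <- setdiff(names(layout), "angle")
  semg <- do.call(rbind, lapply(ch, parse_col))
  rownames(semg) <- ch
  emg_recording(semg, parse_col("angle"), fs = fs,
                subject_id = subject_id, group = group, motion = motion,
                channel_names = ch)
}

#' Write a recording as delimited text
#'
#' Writes channels and the angle trace as tab-delimited columns with a
#' header line. Values are serialized with 17 significant digits so a
#' write-then-read round trip is bit-identical.
#'
#' @param recording An [emg_recording()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  mat <- rbind(recording$semg, angle = recording$angle)
  txt <- apply(mat, 2, format_full)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rownames(mat), collapse = "\t"), con)
  writeLines(apply(txt, 2, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with columns `path`, `subject_id`, `group`,
#' `motion` listing one recording per row. Relative paths are resolved
#' against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return A data frame with one row per recording.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("path", "subject_id", "group", "motion")
  miss <- setdiff(req, names(man))
  if (length(miss)) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  }
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  man
}

#' Load every recording listed in a manifest
#'
#' @param manifest Data frame from [read_manifest()] (or a manifest path).
#' @param layout Column layout passed to [read_recording()].
#' @param fs Sampling rate in Hz.
#' @return List of [emg_recording()] objects.
#' @export
load_cohort <- function(manifest, layout, fs = 1000) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i) {
    read_recording(manifest$path[i], layout,
                   subject_id = manifest$subject_id[i],
                   group = manifest$group[i], motion = manifest$motion[i],
                   fs = fs)
  })
}

#' Write a feature table to CSV at full precision
#'
#' @param features Data frame of per-window features plus label columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  out <- features
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], format_full)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return Data frame with numeric feature columns restored.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a report object as JSON
#'
#' @param report A list-like report (e.g. a classification report).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
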