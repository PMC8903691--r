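# On-disk recording container: a raw little-endian float64 stream (.dat)
# next to a JSON sidecar (.json) declaring dims, sampling rate, group,
# clinical covariates, channel geometry and (for synthetic data) ground
# truth. A manifest CSV indexes a cohort directory.

#' Write one recording to a directory
#'
#' @param rec a `recording`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the path prefix written.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prefix <- file.path(dir, rec$subject_id)
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 8L, endian = "little")
  sidecar <- list(
    dims = dim(rec$data), sfreq = rec$sfreq,
    trigger_sample = rec$trigger_sample,
    channel_positions = rec$channel_positions,
    group = rec$group, clinical = rec$clinical,
    subject_id = rec$subject_id, ground_truth = rec$ground_truth
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a recording container written by [write_recording()]
#'
#' @param prefix path prefix (without `.dat`/`.json`).
#' @return A `recording`.
#' @export
read_recording <- function(prefix) {
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"),
                                 simplifyVector = TRUE)
  dims <- as.integer(sidecar$dims)
  con <- file(paste0(prefix, ".dat"), "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = prod(dims), size = 8L,
                  endian = "little")
  gt <- sidecar$ground_truth
  if (!is.null(gt$source_positions)) {
    gt$source_positions <- as.matrix(gt$source_positions)
  }
  structure(
    list(data = array(vals, dims), sfreq = sidecar$sfreq,
         trigger_sample = sidecar$trigger_sample,
         channel_positions = as.matrix(sidecar$channel_positions),
         group = sidecar$group,
         clinical = as.list(sidecar$clinical),
         subject_id = sidecar$subject_id, ground_truth = gt),
    class = "recording")
}

#' Import and validate a recording container
#'
#' Validation wrapper around [read_recording()]: checks shape consistency,
#' a positive sampling rate, in-range triggers and finite data, failing
#' with an actionable message. Missing clinical covariates are accepted as
#' `NA` and flagged.
#'
#' @param prefix path prefix (without `.dat`/`.json`).
#' @return A validated `recording`.
#' @export
import_recording <- function(prefix) {
  rec <- read_recording(prefix)
  dims <- dim(rec$data)
  if (length(dims) != 3L) stop("data must be channels x samples x trials")
  if (is.null(rec$sfreq) || rec$sfreq <= 0) {
    stop("sidecar sfreq must be a positive sampling rate")
  }
  if (any(rec$trigger_sample < 1) || any(rec$trigger_sample > dims[2L])) {
    stop("trigger_sample outside [1, samples]")
  }
  if (nrow(rec$channel_positions) != dims[1L]) {
    stop("channel_positions rows must match channel count")
  }
  if (!all(is.finite(rec$data))) stop("non-finite values in recording data")
  expected <- c("history_years", "freq_per_month", "duration_hours",
                "vas", "ham_a", "ham_d")
  missing <- setdiff(expected, names(rec$clinical))
  if (length(missing)) {
    rec$clinical[missing] <- NA_real_
    attr(rec, "missing_clinical") <- missing
  }
  rec
}

#' Write a cohort with a manifest
#'
#' @param recs list of `recording` objects.
#' @param dir output directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(recs, dir) {
  for (r in recs) write_recording(r, dir)
  manifest <- data.frame(
    subject = vapply(recs, function(r) r$subject_id, character(1)),
    group = vapply(recs, function(r) r$group, character(1)),
    n_trials = vapply(recs, function(r) dim(r$data)[3L], integer(1)),
    edge_present = vapply(recs, function(r) {
      isTRUE(r$ground_truth$edge_present)
    }, logical(1))
  )
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.csv`.
#' @return List of `recording` objects.
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  lapply(manifest$subject, function(s) import_recording(file.path(dir, s)))
}
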