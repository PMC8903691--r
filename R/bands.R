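#' Canonical MEG frequency bands
#'
#' The five analysis bands used throughout the pipeline: delta (1-4 Hz),
#' theta (4-8 Hz), alpha (8-12 Hz), beta (13-30 Hz), gamma (30-90 Hz).
#'
#' @return A data frame with columns `name`, `lo`, `hi` (Hz).
#' @export
#' @examples
#' canonical_bands()
canonical_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    lo   = c(1, 4, 8, 13, 30),
    hi   = c(4, 8, 12, 30, 90),
    stringsAsFactors = FALSE
  )
}

#' Define a frequency band
#'
#' Builds a `band_definition` object. With only `name` given, the band edges
#' are looked up in [canonical_bands()]; custom edges may be supplied for
#' non-canonical bands.
#'
#' @param name band name; one of delta/theta/alpha/beta/gamma unless custom
#'   edges are given.
#' @param lo,hi band edges in Hz (optional for canonical names).
#' @return A list of class `band_definition` with fields `name`, `lo`, `hi`.
#' @export
#' @examples
#' band_definition("gamma")
#' band_definition("wideband", 1, 90)
band_definition <- function(name, lo = NULL, hi = NULL) {
  if (is.null(lo) || is.null(hi)) {
    bands <- canonical_bands()
    row <- bands[bands$name == name, ]
    if (nrow(row) != 1L) {
      stop("unknown band '", name, "'; give lo/hi explicitly for custom bands")
    }
    lo <- row$lo
    hi <- row$hi
  }
  if (!(lo < hi)) stop("band edges must satisfy lo < hi")
  structure(list(name = name, lo = lo, hi = hi), class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band %s: %g-%g Hz>\n", x$name, x$lo, x$hi))
  invisible(x)
}

#' Epoch analysis window relative to the stimulus trigger
#'
#' The default window of 90-180 ms after the trigger covers the main
#' event-related neuromagnetic components.
#'
#' @param start_ms,end_ms window edges in milliseconds relative to trigger.
#' @return A list of class `epoch_window`.
#' @export
epoch_window <- function(start_ms = 90, end_ms = 180) {
  if (!(start_ms < end_ms)) stop("window must satisfy start_ms < end_ms")
  structure(list(start_ms = start_ms, end_ms = end_ms), class = "epoch_window")
}
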