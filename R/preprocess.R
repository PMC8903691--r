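#' Remove the per-channel DC offset
#'
#' Subtracts each channel's mean so every row of the output is zero-mean.
#'
#' @param data channels x samples numeric matrix.
#' @return Matrix of the same shape with per-channel mean removed.
#' @export
remove_dc <- function(data) {
  data <- as.matrix(data)
  bad <- which(!apply(data, 1L, function(r) all(is.finite(r))))
  if (length(bad)) {
    stop("non-finite values in channel(s): ", paste(bad, collapse = ", "))
  }
  data - rowMeans(data)
}

# Butterworth band filter designed directly in second-order sections.
# The flat transfer-function polynomial of an order-8 band filter is
# numerically ill-conditioned at narrow normalized bands (1-4 Hz at 1 kHz);
# a biquad cascade built from the analog prototype (prewarp -> lowpass-to-
# band transform -> bilinear per conjugate pole pair) stays near machine
# precision across all band/sampling-rate combinations used here.
butter_sos <- function(order, w, type = c("pass", "stop")) {
  type <- match.arg(type)
  stopifnot(length(w) == 2L, all(w > 0), all(w < 1), w[1] < w[2],
            order %% 2 == 0)
  wl <- tan(pi * w[1] / 2)           # prewarped analog edges (T = 2)
  wh <- tan(pi * w[2] / 2)
  w0 <- sqrt(wl * wh)
  bw <- wh - wl
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # Re < 0
  s_poles <- unlist(lapply(proto, function(p) {
    if (type == "pass") {
      disc <- sqrt((p * bw)^2 - 4 * w0^2)
      c((p * bw + disc) / 2, (p * bw - disc) / 2)
    } else {
      q <- bw / p
      disc <- sqrt(q^2 - 4 * w0^2)
      c((q + disc) / 2, (q - disc) / 2)
    }
  }))
  z_poles <- (1 + s_poles) / (1 - s_poles)
  # digital zeros: band-pass has order zeros at z = 1 and order at z = -1;
  # band-stop has order conjugate pairs on the unit circle at the center
  w0d <- 2 * atan(w0)
  sections <- list()
  remaining <- z_poles
  while (length(remaining) >= 2L) {
    i1 <- which.max(abs(Im(remaining)))
    p1 <- remaining[i1]; remaining <- remaining[-i1]
    i2 <- which.min(abs(remaining - Conj(p1)))
    p2 <- remaining[i2]; remaining <- remaining[-i2]
    a <- Re(c(1, -(p1 + p2), p1 * p2))
    b <- if (type == "pass") c(1, 0, -1) else c(1, -2 * cos(w0d), 1)
    sections[[length(sections) + 1L]] <- list(b = b, a = a)
  }
  ref <- if (type == "pass") w0d else 0   # unit gain reference frequency
  zr <- exp(1i * ref)
  H <- prod(vapply(sections, function(s) {
    sum(s$b * zr^-(0:2)) / sum(s$a * zr^-(0:2))
  }, complex(1)))
  sections[[1L]]$b <- sections[[1L]]$b / abs(H)
  structure(list(sections = sections, order = order, w = w, type = type),
            class = "sos_filter")
}

sos_apply <- function(sections, x) {
  for (s in sections) x <- iir_filter_rows(s$b, s$a, x)
  x
}

# Zero-phase (forward-backward) application of an IIR filter to each row,
# with reflected edge padding to suppress start-up transients. The inner
# recursion is compiled; signal::butter supplies the coefficients.
apply_filtfilt <- function(data, filt) {
  data <- as.matrix(data)
  n <- ncol(data)
  npad <- min(n - 1L, 24L * filt$order)
  pre <- 2 * data[, 1L] - data[, npad + 1L - seq_len(npad) + 1L, drop = FALSE]
  post <- 2 * data[, n] - data[, n - seq_len(npad), drop = FALSE]
  ext <- cbind(pre, data, post)
  y <- sos_apply(filt$sections, ext)
  y <- sos_apply(filt$sections, y[, rev(seq_len(ncol(y))), drop = FALSE])
  y <- y[, rev(seq_len(ncol(y))), drop = FALSE]
  out <- y[, npad + seq_len(n), drop = FALSE]
  dimnames(out) <- dimnames(data)
  out
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase lag).
#'
#' @param data channels x samples matrix.
#' @param sfreq sampling rate, Hz.
#' @param band a [band_definition()].
#' @return Filtered matrix, same shape.
#' @export
bandpass <- function(data, sfreq, band) {
  stopifnot(inherits(band, "band_definition"))
  nyq <- sfreq / 2
  if (band$hi >= nyq) {
    stop(sprintf("band edge %g Hz violates Nyquist (%g Hz at sfreq %g)",
                 band$hi, nyq, sfreq))
  }
  bf <- butter_sos(4, c(band$lo, band$hi) / nyq, "pass")
  apply_filtfilt(data, bf)
}

#' Zero-phase notch filter for power-line noise
#'
#' Band-stop Butterworth centred on `freq` (default 50 Hz), applied
#' forward-backward.
#'
#' @param data channels x samples matrix.
#' @param sfreq sampling rate, Hz.
#' @param freq line frequency to suppress, Hz.
#' @param half_width half width of the stop band, Hz.
#' @return Filtered matrix, same shape.
#' @export
notch <- function(data, sfreq, freq = 50, half_width = 2) {
  nyq <- sfreq / 2
  if (freq + half_width >= nyq) stop("notch band violates Nyquist")
  bf <- butter_sos(4, c(freq - half_width, freq + half_width) / nyq, "stop")
  apply_filtfilt(data, bf)
}

window_samples <- function(window, sfreq, trigger_sample) {
  i0 <- trigger_sample + round(window$start_ms / 1000 * sfreq)
  i1 <- trigger_sample + round(window$end_ms / 1000 * sfreq) - 1L
  seq.int(i0, i1)
}

#' Epoch, reject artifact trials, and average
#'
#' Extracts the analysis window from every trial, drops trials whose peak
#' absolute amplitude exceeds `reject`, and averages the survivors.
#'
#' @param data channels x samples x trials array.
#' @param sfreq sampling rate, Hz.
#' @param trigger_samples 1-based trigger sample index per trial (scalar is
#'   recycled).
#' @param window an [epoch_window()].
#' @param reject peak-amplitude rejection threshold (same units as `data`);
#'   `Inf` disables rejection. `NULL` uses 5x the median per-channel robust SD.
#' @return List with `average` (channels x window samples), `n_kept`,
#'   `kept` (logical per trial), and `windows` (list of kept trial windows).
#' @export
epoch_and_average <- function(data, sfreq, trigger_samples, window = epoch_window(),
                              reject = Inf) {
  stopifnot(length(dim(data)) == 3L)
  n_trials <- dim(data)[3L]
  trigger_samples <- rep_len(as.integer(trigger_samples), n_trials)
  if (is.null(reject)) {
    rsd <- apply(data, 1L, function(ch) median(abs(ch)) * 1.4826)
    reject <- 5 * median(rsd)
  }
  windows <- vector("list", n_trials)
  kept <- logical(n_trials)
  for (tr in seq_len(n_trials)) {
    idx <- window_samples(window, sfreq, trigger_samples[tr])
    if (idx[1L] < 1L || idx[length(idx)] > dim(data)[2L]) {
      stop("analysis window falls outside trial ", tr)
    }
    w <- data[, idx, tr, drop = FALSE]
    dim(w) <- dim(w)[1:2]
    windows[[tr]] <- w
    kept[tr] <- max(abs(w)) <= reject
  }
  if (!any(kept)) stop("all trials rejected; no data to average")
  avg <- Reduce(`+`, windows[kept]) / sum(kept)
  list(average = avg, n_kept = sum(kept), kept = kept, windows = windows[kept])
}

#' Head-movement exclusion rule
#'
#' A subject is dropped when the measured head movement exceeds the limit;
#' movement of exactly the limit is kept (strictly "beyond").
#'
#' @param movement_mm measured head movement, mm.
#' @param limit_mm exclusion limit, mm (default 5).
#' @return `TRUE` to keep the subject, `FALSE` to drop.
#' @export
exclude_by_movement <- function(movement_mm, limit_mm = 5) {
  stopifnot(movement_mm >= 0)
  keep <- movement_mm <= limit_mm
  if (!keep) {
    message(sprintf("subject dropped: head movement %.2f mm > %.2f mm",
                    movement_mm, limit_mm))
  }
  keep
}

#' Full per-recording preprocessing for one band
#'
#' DC removal, 50 Hz notch, band-pass into `band`, then epoching with
#' artifact rejection. Filtering is done on the full trial segments before
#' the 90-180 ms window is cut, so filter edge transients stay outside the
#' analysis window.
#'
#' @param rec a `recording` (see [generate_cohort()] / [import_recording()]).
#' @param band a [band_definition()].
#' @param window an [epoch_window()].
#' @param reject artifact rejection threshold; see [epoch_and_average()].
#' @param notch_freq line frequency, Hz; `NA` skips the notch (useful when
#'   the band lies entirely below it).
#' @return As [epoch_and_average()].
#' @export
preprocess_recording <- function(rec, band, window = epoch_window(),
                                 reject = Inf, notch_freq = 50) {
  stopifnot(inherits(rec, "recording"))
  dims <- dim(rec$data)
  filt_one <- function(x) {
    x <- remove_dc(x)
    if (!is.na(notch_freq) && notch_freq + 2 < rec$sfreq / 2) {
      x <- notch(x, rec$sfreq, notch_freq)
    }
    bandpass(x, rec$sfreq, band)
  }
  if (isTRUE(rec$contiguous_trials)) {
    # trials are adjacent segments of one continuous run: filter the
    # stitched record once (no per-trial edge transients), then re-cut
    flat <- filt_one(matrix(rec$data, dims[1L], dims[2L] * dims[3L]))
    out <- array(flat, dims)
  } else {
    out <- rec$data
    for (tr in seq_len(dims[3L])) out[, , tr] <- filt_one(out[, , tr])
  }
  epoch_and_average(out, rec$sfreq, rec$trigger_sample, window, reject)
}
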