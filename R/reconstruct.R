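#' Volumetric source grid
#'
#' @param positions voxels x 3 matrix of grid positions, meters.
#' @param spacing grid spacing in meters (default 0.006, i.e. 6 mm).
#' @param region_labels per-voxel label from PFC/TL/OCC/OTHER.
#' @return A `source_grid` object.
#' @export
source_grid <- function(positions, spacing = 0.006, region_labels = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3L, spacing > 0)
  if (is.null(region_labels)) region_labels <- rep("OTHER", nrow(positions))
  stopifnot(length(region_labels) == nrow(positions))
  dd <- dist(positions)
  if (nrow(positions) > 1L && min(dd) < 1e-9) {
    stop("grid positions must be pairwise distinct")
  }
  structure(list(positions = positions, spacing = spacing,
                 region_labels = region_labels),
            class = "source_grid")
}

#' LCMV beamformer weights for one source
#'
#' Unit-gain, minimum-variance spatial filter
#' \deqn{w = \frac{(C + \lambda I)^{-1} g}{g^\top (C + \lambda I)^{-1} g}}
#' with diagonal loading \eqn{\lambda = \mathrm{reg} \cdot
#' \mathrm{mean}(\mathrm{diag}(C))}.
#'
#' @param cov channels x channels sensor covariance (symmetric).
#' @param gain_column channels-long forward gain vector for the source.
#' @param reg regularization fraction (default 0.05).
#' @return Weight vector `w` with `sum(w * gain_column) == 1`.
#' @export
lcmv_weights <- function(cov, gain_column, reg = 0.05) {
  cov <- as.matrix(cov)
  stopifnot(isSymmetric(unname(cov), tol = 1e-8))
  g <- as.numeric(gain_column)
  if (sqrt(sum(g^2)) < 1e-12) stop("gain_column must be nonzero")
  creg <- cov + reg * mean(diag(cov)) * diag(nrow(cov))
  cg <- tryCatch(solve(creg, g), error = function(e) {
    stop("regularized covariance is singular; increase reg")
  })
  cg / sum(g * cg)
}

#' Scan a source grid with the LCMV beamformer
#'
#' Computes one virtual-sensor waveform per grid voxel and records per-voxel
#' output power for downstream peak selection and merging.
#'
#' @param sensor_data channels x samples matrix.
#' @param gain channels x voxels forward gain matrix (one column per voxel).
#' @param grid the [source_grid()] the gain columns correspond to.
#' @param reg regularization fraction for [lcmv_weights()].
#' @param band optional [band_definition()] recorded on the output.
#' @param subject_id optional identifier recorded on the output.
#' @return A `virtual_sensor_set`: list with `signals` (voxels x samples),
#'   `power`, `grid`, `band`, `subject_id`.
#' @export
scan_grid <- function(sensor_data, gain, grid, reg = 0.05, band = NULL,
                      subject_id = NULL) {
  sensor_data <- as.matrix(sensor_data)
  gain <- as.matrix(gain)
  if (ncol(gain) != nrow(grid$positions)) {
    stop("gain column count must match grid size")
  }
  if (nrow(gain) != nrow(sensor_data)) {
    stop("gain rows must match sensor channel count")
  }
  C <- cov(t(sensor_data))
  W <- vapply(seq_len(ncol(gain)),
              function(j) lcmv_weights(C, gain[, j], reg),
              numeric(nrow(gain)))
  signals <- t(W) %*% sensor_data
  structure(list(signals = signals,
                 power = rowMeans(signals^2),
                 grid = grid, band = band, subject_id = subject_id),
            class = "virtual_sensor_set")
}

#' Merge voxels closer than a minimum distance
#'
#' Greedy agglomeration in descending output-power order: a voxel strictly
#' closer than `min_dist` to an already-retained voxel is absorbed into it
#' (its signal is discarded, the membership is logged). Exactly `min_dist`
#' separation keeps both voxels. Ties in power break toward the lower voxel
#' index. Idempotent.
#'
#' @param vs a `virtual_sensor_set` from [scan_grid()].
#' @param min_dist merge radius in meters (default 0.010, i.e. 10 mm).
#' @return A `virtual_sensor_set` on the retained voxels, with a `merged`
#'   data frame logging absorbed voxels.
#' @export
merge_close_voxels <- function(vs, min_dist = 0.010) {
  stopifnot(inherits(vs, "virtual_sensor_set"))
  pos <- vs$grid$positions
  n <- nrow(pos)
  ord <- order(-vs$power, seq_len(n))  # power desc, then lowest index
  retained <- integer(0)
  absorbed_into <- rep(NA_integer_, n)
  for (v in ord) {
    if (length(retained)) {
      dists <- sqrt(rowSums((pos[retained, , drop = FALSE] -
                               matrix(pos[v, ], length(retained), 3,
                                      byrow = TRUE))^2))
      hit <- which(dists < min_dist)
      if (length(hit)) {
        absorbed_into[v] <- retained[hit[which.min(dists[hit])]]
        next
      }
    }
    retained <- c(retained, v)
  }
  retained <- sort(retained)
  merged <- data.frame(voxel = which(!is.na(absorbed_into)),
                       into = absorbed_into[!is.na(absorbed_into)])
  structure(list(signals = vs$signals[retained, , drop = FALSE],
                 power = vs$power[retained],
                 grid = source_grid(pos[retained, , drop = FALSE],
                                    vs$grid$spacing,
                                    vs$grid$region_labels[retained]),
                 band = vs$band, subject_id = vs$subject_id,
                 retained = retained, merged = merged),
            class = "virtual_sensor_set")
}

#' @export
print.virtual_sensor_set <- function(x, ...) {
  cat(sprintf("<virtual sensors: %d voxels x %d samples%s>\n",
              nrow(x$signals), ncol(x$signals),
              if (!is.null(x$band)) paste0(", band ", x$band$name) else ""))
  invisible(x)
}

#' Reconstruct virtual sensors from a set of trial windows
#'
#' Convenience wrapper used by the pipeline: concatenates the per-trial
#' analysis windows, estimates the sensor covariance once, scans the grid,
#' and applies the voxel-merging rule. Returns both the merged set computed
#' on the concatenated windows and the per-trial window count so downstream
#' stages can un-concatenate.
#'
#' @param windows list of channels x window-samples matrices (kept trials).
#' @param gain channels x voxels gain matrix.
#' @param grid a [source_grid()].
#' @param reg regularization fraction.
#' @param min_dist voxel-merge radius, meters.
#' @param band,subject_id metadata recorded on the result.
#' @return A merged `virtual_sensor_set`; attribute `window_len` gives the
#'   per-trial window length in samples.
#' @export
reconstruct_windows <- function(windows, gain, grid, reg = 0.05,
                                min_dist = 0.010, band = NULL,
                                subject_id = NULL) {
  concat <- do.call(cbind, windows)
  vs <- scan_grid(concat, gain, grid, reg = reg, band = band,
                  subject_id = subject_id)
  vs <- merge_close_voxels(vs, min_dist)
  attr(vs, "window_len") <- ncol(windows[[1L]])
  vs
}
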