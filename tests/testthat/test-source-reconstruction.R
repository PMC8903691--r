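test_that("LCMV weights satisfy the unit-gain constraint", {
  # identity covariance, gain e1: weights reduce to e1
  w <- lcmv_weights(diag(4), c(1, 0, 0, 0), reg = 0)
  expect_equal(w, c(1, 0, 0, 0), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    M <- matrix(rnorm(n * n), n)
    C <- crossprod(M) / n + diag(n)
    g <- rnorm(n)
    w <- lcmv_weights(C, g, reg = 0.05)
    expect_equal(sum(w * g), 1, tolerance = 1e-9)
  }
  expect_error(lcmv_weights(diag(3), rep(0, 3)), "nonzero")
})

test_that("a lone noiseless source is reconstructed exactly", {
  set.seed(12)
  geom <- megnet:::default_geometry(20, 3, 12)
  gain <- make_gain_matrix(20, geom$sources, geom$channels, seed = 2)
  src <- matrix(rnorm(500), 1)
  sens <- gain[, 2, drop = FALSE] %*% src
  C <- tcrossprod(sens) / ncol(sens) + 1e-12 * diag(20)
  w <- lcmv_weights(C, gain[, 2], reg = 0)
  expect_equal(as.numeric(crossprod(w, sens)), as.numeric(src),
               tolerance = 1e-6)
})

test_that("grid scan localizes sources and is permutation-equivariant", {
  set.seed(13)
  geom <- megnet:::default_geometry(30, 5, 13)
  gain <- make_gain_matrix(30, geom$sources, geom$channels, seed = 3)
  src <- matrix(rnorm(800), 1)
  sens <- gain[, 4, drop = FALSE] %*% src
  grid <- source_grid(geom$sources)
  vs <- scan_grid(sens, gain, grid, reg = 1e-8)
  expect_equal(which.max(vs$power), 4)
  expect_error(scan_grid(sens, gain[, 1:3], grid), "grid size")

  perm <- c(3, 1, 5, 2, 4)
  grid_p <- source_grid(geom$sources[perm, ])
  vs_p <- scan_grid(sens, gain[, perm], grid_p, reg = 1e-8)
  expect_equal(vs_p$signals, vs$signals[perm, ], tolerance = 1e-10)
})

test_that("beamformer separates two planted sources at 10 dB SNR", {
  hits <- 0
  for (s in 1:25) {
    geom <- megnet:::default_geometry(50, 2, s)
    gain <- make_gain_matrix(50, geom$sources, geom$channels, seed = s)
    A <- array(0, c(2, 2, 1)); diag(A[, , 1]) <- 0.3
    src <- simulate_mvar(source_network_spec(A), 1000, seed = 900 + s)
    sens <- gain %*% src
    noise_sd <- sqrt(mean(sens^2) / 10)
    set.seed(40 + s)
    sens <- sens + noise_sd * matrix(rnorm(length(sens)), 50)
    vs <- scan_grid(sens, gain, source_grid(geom$sources), reg = 0.05)
    cc <- c(abs(cor(vs$signals[1, ], src[1, ])),
            abs(cor(vs$signals[2, ], src[2, ])))
    hits <- hits + all(cc > 0.9)
  }
  expect_gte(hits, 23)
})

test_that("two active sources surface as the two top power peaks in a grid scan", {
  hits <- 0; n_runs <- 30
  for (s in 1:n_runs) {
    set.seed(3100 + s)
    # two true sources 40 mm apart plus inactive decoy voxels
    true_pos <- rbind(c(-0.02, 0, 0.01), c(0.02, 0, 0.01))
    decoys <- matrix(runif(28 * 3, -0.05, 0.05), 28, 3)
    keep <- apply(decoys, 1, function(p) {
      all(sqrt(colSums((t(true_pos) - p)^2)) > 0.012)
    })
    pos <- rbind(true_pos, decoys[keep, ])
    chan <- megnet:::default_geometry(50, 2, 3100 + s)$channels
    gain <- make_gain_matrix(50, pos, chan, seed = 3100 + s)
    A <- array(0, c(2, 2, 1)); diag(A[, , 1]) <- 0.3
    src <- simulate_mvar(source_network_spec(A), 1000, seed = 3200 + s)
    sens <- gain[, 1:2] %*% src
    noise_sd <- sqrt(mean(sens^2) / 10)
    set.seed(3300 + s)
    sens <- sens + noise_sd * matrix(rnorm(length(sens)), 50)
    vs <- scan_grid(sens, gain, source_grid(pos), reg = 0.05)
    hits <- hits + setequal(order(-vs$power)[1:2], 1:2)
  }
  expect_gte(hits, round(0.9 * n_runs))
})

test_that("voxel merging follows the strict 10 mm rule with power priority", {
  mk_vs <- function(pos, power) {
    structure(list(signals = matrix(rnorm(nrow(pos) * 10), nrow(pos)),
                   power = power, grid = source_grid(pos),
                   band = NULL, subject_id = NULL),
              class = "virtual_sensor_set")
  }
  # 6 mm apart: merged, higher power retained
  vs <- mk_vs(rbind(c(0, 0, 0), c(0.006, 0, 0)), c(1, 2))
  m <- merge_close_voxels(vs)
  expect_equal(nrow(m$grid$positions), 1)
  expect_equal(m$grid$positions[1, 1], 0.006)
  # 12 mm apart: both kept
  m2 <- merge_close_voxels(mk_vs(rbind(c(0, 0, 0), c(0.012, 0, 0)), c(1, 2)))
  expect_equal(nrow(m2$grid$positions), 2)
  # exactly 10 mm: strict "less than" keeps both
  m3 <- merge_close_voxels(mk_vs(rbind(c(0, 0, 0), c(0.010, 0, 0)), c(1, 2)))
  expect_equal(nrow(m3$grid$positions), 2)
  # collinear 0/6/12 mm with descending power: 0 and 12 mm survive
  vs4 <- mk_vs(rbind(c(0, 0, 0), c(0.006, 0, 0), c(0.012, 0, 0)), c(3, 2, 1))
  m4 <- merge_close_voxels(vs4)
  expect_equal(sort(m4$retained), c(1, 3))
  expect_equal(m4$merged$voxel, 2)
  expect_equal(m4$merged$into, 1)
})

test_that("voxel merging is idempotent", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    pos <- matrix(runif(n * 3, 0, 0.04), n, 3)
    vs <- structure(list(signals = matrix(rnorm(n * 20), n),
                         power = runif(n), grid = source_grid(pos),
                         band = NULL, subject_id = NULL),
                    class = "virtual_sensor_set")
    m1 <- merge_close_voxels(vs)
    m2 <- merge_close_voxels(m1)
    expect_equal(m2$grid$positions, m1$grid$positions)
    expect_equal(m2$signals, m1$signals)
    dd <- dist(m1$grid$positions)
    if (length(dd)) expect_gte(min(dd), 0.010)
  }
})
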