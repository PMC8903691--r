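test_that("white-noise MVAR realization is serially uncorrelated", {
  spec <- source_network_spec(matrix(0, 3, 3))
  x <- simulate_mvar(spec, 4000, seed = 1)
  expect_equal(dim(x), c(3, 4000))
  for (i in 1:3) {
    ac1 <- cor(x[i, -1], x[i, -4000])
    expect_lt(abs(ac1), 3 / sqrt(4000))
  }
})

test_that("planted VAR(1) coupling shows up in the lag-1 cross-correlation", {
  # y(t) = 0.5 x(t-1) + e: Lyapunov solution gives var x = 1,
  # var y = 1.25, cov(y_t, x_{t-1}) = 0.5, so corr = 0.5/sqrt(1.25) = 0.447
  A <- matrix(c(0, 0, 0.5, 0), 2, 2, byrow = TRUE)
  x <- simulate_mvar(source_network_spec(A), 8000, seed = 3)
  fwd <- cor(x[2, -1], x[1, -8000])
  rev <- cor(x[1, -1], x[2, -8000])
  expect_equal(fwd, 0.5 / sqrt(1.25), tolerance = 0.05)
  expect_lt(abs(rev), 3 / sqrt(8000))
})

test_that("simulation is deterministic and rejects unstable specs", {
  A <- matrix(c(0.5, 0.2, 0.1, 0.4), 2, 2)
  spec <- source_network_spec(A)
  x1 <- simulate_mvar(spec, 500, seed = 42)
  x2 <- simulate_mvar(spec, 500, seed = 42)
  expect_identical(x1, x2)
  expect_error(source_network_spec(diag(2) * 1.01), "spectral radius")
  expect_error(source_network_spec(diag(2), noise_cov = matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(simulate_mvar(spec, 5, seed = 1), "n_samples")
})

test_that("stability gate holds over random nearly-critical specs", {
  set.seed(9)
  for (i in 1:25) {
    d <- sample(2:5, 1)
    A <- matrix(rnorm(d * d, sd = 0.4), d, d)
    rho <- companion_spectral_radius(array(A, c(d, d, 1)))
    if (rho >= 1) {
      expect_error(source_network_spec(A), "spectral radius")
    } else {
      spec <- source_network_spec(A)
      expect_lt(spec$spectral_radius, 1)
      x <- simulate_mvar(spec, 300, seed = i)
      expect_true(all(is.finite(x)))
    }
  }
})

test_that("gain matrix has unit-norm full-rank distance-decaying columns", {
  set.seed(5)
  src <- matrix(runif(6, -0.05, 0.05), 2, 3)
  chan <- matrix(runif(30, -0.1, 0.1), 10, 3)
  G <- make_gain_matrix(10, src, chan, seed = 1)
  expect_equal(qr(G)$rank, 2)
  expect_equal(colSums(G^2), c(1, 1), tolerance = 1e-12)
  expect_error(make_gain_matrix(10, rbind(src[1, ], src[1, ]), chan),
               "duplicate")
  # magnitude decays with distance on average: nearest channel louder than
  # farthest (orientation jitter preserved the distance kernel)
  d1 <- sqrt(rowSums((chan - matrix(src[1, ], 10, 3, byrow = TRUE))^2))
  expect_gt(mean(abs(G[order(d1)[1:3], 1])), mean(abs(G[order(-d1)[1:3], 1])))
})

test_that("degenerate prevalences plant the edge exactly per group", {
  net <- smoke_network()
  cs <- smoke_cohort_spec(n_patients = 4, n_controls = 4, seed = 11,
                          pattern_prevalence_patients = 1,
                          pattern_prevalence_controls = 0,
                          n_trials = 2, trial_samples = 60)
  recs <- generate_cohort(cs, net)
  present <- vapply(recs, function(r) r$ground_truth$edge_present, logical(1))
  groups <- vapply(recs, function(r) r$group, character(1))
  expect_true(all(present[groups == "patient"]))
  expect_false(any(present[groups == "control"]))
})

test_that("planted prevalence counts match their binomial expectation", {
  # mean per-group presence counts over seeded cohorts within 2 SE of
  # 24 * 19/24 = 19 and 24 * 8/24 = 8 (presence flags only; no signal run)
  n_rep <- 2000
  counts <- t(vapply(seq_len(n_rep), function(i) {
    asg <- draw_cohort_assignments(cohort_spec(seed = i))
    c(sum(asg$edge_present[asg$group == "patient"]),
      sum(asg$edge_present[asg$group == "control"]))
  }, numeric(2)))
  se_p <- sqrt(24 * (19 / 24) * (5 / 24)) / sqrt(n_rep)
  se_c <- sqrt(24 * (8 / 24) * (16 / 24)) / sqrt(n_rep)
  expect_lt(abs(mean(counts[, 1]) - 19), 2 * se_p)
  expect_lt(abs(mean(counts[, 2]) - 8), 2 * se_c)
})

test_that("cohort generation is deterministic and meets the requested SNR", {
  net <- smoke_network()
  cs <- smoke_cohort_spec(n_patients = 2, n_controls = 1, seed = 21,
                          n_trials = 4, trial_samples = 100)
  r1 <- generate_cohort(cs, net)
  r2 <- generate_cohort(cs, net)
  expect_identical(r1[[1]]$data, r2[[1]]$data)
  expect_identical(r1[[3]]$clinical, r2[[3]]$clinical)
  expect_true(all(vapply(r1, function(r) all(is.finite(r$data)), logical(1))))

  # SNR audit: regenerate the subject's noiseless sensor signal and check
  # the realized variance-ratio SNR within 1 dB of the request
  gt <- r1[[1]]$ground_truth
  net_i <- megnet:::scale_network(
    if (gt$edge_present) net else drop_coupling(net, 1, 2), gt$net_scale)
  src <- simulate_mvar(net_i, cs$n_trials * cs$trial_samples,
                       seed = megnet:::derive_seed(cs$seed, 101),
                       sfreq = cs$sfreq)
  gain <- make_gain_matrix(cs$n_channels, gt$source_positions,
                           r1[[1]]$channel_positions, seed = 1)
  clean <- gain %*% src
  noise <- matrix(r1[[1]]$data, cs$n_channels) - clean
  expect_lt(abs(snr_db_of(clean, noise) - cs$snr_db), 1)
})

test_that("copula covariate attains the target Spearman correlation", {
  set.seed(31)
  n_rep <- 400
  rhos <- vapply(seq_len(n_rep), function(i) {
    anchor <- runif(24)
    y <- copula_covariate(anchor, -0.5, location = 10, scale = 5)
    cor(anchor, y, method = "spearman")
  }, numeric(1))
  expect_gt(mean(rhos), -0.56)
  expect_lt(mean(rhos), -0.44)
})

test_that("Nyquist violations in cohort generation are rejected", {
  net <- smoke_network(band = band_definition("gamma"))
  cs <- smoke_cohort_spec(n_patients = 1, n_controls = 0, seed = 1,
                          sfreq = 100)
  expect_error(generate_cohort(cs, net), "Nyquist")
})
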