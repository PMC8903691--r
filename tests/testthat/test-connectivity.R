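test_that("pairwise correlation matches the covariance/SD ratio", {
  x <- rbind(a = c(1, 2, 3), b = c(1, 2, 4))
  R <- pairwise_correlation(x)
  expect_equal(R[1, 2], 9 / sqrt(84), tolerance = 1e-12)
  expect_equal(R[1, 2], cor(c(1, 2, 3), c(1, 2, 4)))
  y <- matrix(rnorm(300), 3)
  y[2, ] <- -y[1, ]
  R2 <- pairwise_correlation(y)
  expect_equal(R2[1, 2], -1)
  expect_equal(diag(R2), rep(1, 3))
  expect_true(isSymmetric(R2))
})

test_that("zero-variance sources are excluded with a warning, not NaN", {
  x <- rbind(rnorm(50), rep(2, 50), rnorm(50))
  expect_warning(R <- pairwise_correlation(x), "zero-variance")
  expect_true(all(is.na(R[2, ])))
  expect_false(anyNA(R[c(1, 3), c(1, 3)]))
  expect_equal(attr(R, "excluded"), 2)
})

test_that("t thresholding reproduces the closed-form t values", {
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  th <- t_threshold(R, K = 18)
  expect_equal(th$Tp[1, 2], 0.5 * sqrt(16 / 0.75), tolerance = 1e-12)
  expect_equal(th$Tp[1, 2], 2.3094, tolerance = 1e-4)
  z <- t_threshold(matrix(c(1, 0, 0, 1), 2), K = 100)
  expect_equal(z$Tp[1, 2], 0)
  expect_false(z$adjacency[1, 2])
  expect_error(t_threshold(R, K = 2), "K")
  # minimal retained |R| at K = 540, alpha = 0.01
  tq <- qt(0.995, 538)
  r_min <- tq / sqrt(538 + tq^2)
  expect_equal(r_min, 0.1108, tolerance = 1e-3)
  just_below <- matrix(c(1, r_min * 0.999, r_min * 0.999, 1), 2)
  just_above <- matrix(c(1, r_min * 1.001, r_min * 1.001, 1), 2)
  expect_false(t_threshold(just_below, 540)$adjacency[1, 2])
  expect_true(t_threshold(just_above, 540)$adjacency[1, 2])
})

test_that("Tp-based retention is equivalent to direct t-CDF evaluation", {
  set.seed(61)
  n <- 10000
  R <- runif(n, -0.999, 0.999)
  K <- sample(5:2000, n, replace = TRUE)
  Tp <- R * sqrt((K - 2) / (1 - R^2))
  keep_tp <- 2 * pt(-abs(Tp), K - 2) < 0.01
  keep_cdf <- vapply(seq_len(n), function(i) {
    2 * (1 - pt(abs(R[i]) * sqrt((K[i] - 2) / (1 - R[i]^2)), K[i] - 2)) < 0.01
  }, logical(1))
  expect_identical(keep_tp, keep_cdf)
  # and the package path agrees pair by pair
  for (i in sample(n, 50)) {
    Rm <- matrix(c(1, R[i], R[i], 1), 2)
    th <- t_threshold(Rm, K[i])
    expect_identical(th$adjacency[1, 2], keep_tp[i])
  }
})

test_that("planted directed coupling is recovered and nulls stay undirected", {
  A <- matrix(c(0, 0, 0.5, 0), 2, 2, byrow = TRUE)  # x -> y
  spec <- source_network_spec(A)
  rec <- 0
  for (s in 1:40) {
    x <- simulate_mvar(spec, 2000, seed = 100 + s)
    gd <- granger_direction(x, rbind(c(1L, 2L)), model_order_max = 5)
    rec <- rec + (gd$direction %in% c("a->b", "bidirectional") &&
                    gd$gc_ab > gd$gc_ba)
  }
  expect_gte(rec / 40, 0.95)

  null_spec <- source_network_spec(matrix(0, 2, 2))
  fd <- 0
  for (s in 1:100) {
    x <- simulate_mvar(null_spec, 2000, seed = 700 + s)
    gd <- granger_direction(x, rbind(c(1L, 2L)), model_order_max = 5)
    fd <- fd + (gd$p_ab < 0.05) + (gd$p_ba < 0.05)
  }
  expect_lte(fd / 200, 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("symmetric coupling is classified bidirectional", {
  A <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  x <- simulate_mvar(source_network_spec(A), 3000, seed = 5)
  gd <- granger_direction(x, rbind(c(1L, 2L)), model_order_max = 5)
  expect_equal(gd$direction, "bidirectional")
})

test_that("pairwise and conditional GC agree exactly on 2-node systems", {
  A <- matrix(c(0.2, 0, 0.5, 0.1), 2, 2, byrow = TRUE)
  x <- simulate_mvar(source_network_spec(A), 1500, seed = 9)
  g_cond <- granger_direction(x, rbind(c(1L, 2L)), model_order_max = 4,
                              conditional = TRUE)
  g_pair <- granger_direction(x, rbind(c(1L, 2L)), model_order_max = 4,
                              conditional = FALSE)
  expect_equal(g_cond$gc_ab, g_pair$gc_ab)
  expect_equal(g_cond$gc_ba, g_pair$gc_ba)
  expect_equal(g_cond$p_ab, g_pair$p_ab)
})

test_that("GC statistics are non-negative", {
  set.seed(66)
  for (i in 1:10) {
    A <- matrix(rnorm(9, sd = 0.25), 3, 3)
    if (companion_spectral_radius(array(A, c(3, 3, 1))) >= 1) next
    x <- simulate_mvar(source_network_spec(A), 800, seed = i)
    gd <- granger_direction(x, rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)),
                            model_order_max = 3)
    expect_true(all(gd$gc_ab >= -1e-10 & gd$gc_ba >= -1e-10))
  }
})

test_that("edge signs and node roles follow the correlation and degrees", {
  g <- graph_from_edges(3, a = c(1), b = c(2), R = 0.7,
                        direction = "a->b")
  expect_equal(g$edges$sign, "excitatory")
  expect_equal(g$node_roles, c("driver", "driven", "isolated"))

  g2 <- graph_from_edges(2, 1, 2, R = -0.3, direction = "b->a")
  expect_equal(g2$edges$sign, "inhibitory")
  expect_equal(g2$node_roles, c("driven", "driver"))

  # a -> b and c -> a: a has out 1 in 1 -> mixed
  g3 <- graph_from_edges(3, a = c(1, 3), b = c(2, 1), R = c(0.5, 0.5),
                         direction = c("a->b", "a->b"))
  expect_equal(g3$node_roles, c("mixed", "driven", "driver"))
})

test_that("pattern detection respects direction and region labels", {
  mk <- function(direction) {
    g <- graph_from_edges(3, 1, 2, R = 0.6, direction = direction)
    g$regions <- c("PFC", "TL", "OCC")
    g
  }
  expect_true(detect_pattern(mk("a->b"), "PFC", "TL"))
  expect_false(detect_pattern(mk("b->a"), "PFC", "TL"))
  expect_true(detect_pattern(mk("b->a"), "TL", "PFC"))
  expect_true(detect_pattern(mk("bidirectional"), "PFC", "TL"))
  expect_false(detect_pattern(mk("undirected"), "PFC", "TL"))
})

test_that("the connectivity graph is equivariant to source relabeling", {
  net <- smoke_network()
  cs <- smoke_cohort_spec(n_patients = 1, n_controls = 0, seed = 77,
                          pattern_prevalence_patients = 1)
  rec <- generate_cohort(cs, net)[[1]]
  cfg <- smoke_pipeline_config()
  res <- analyze_recording(rec, "gamma", cfg)
  # relabel sources by permuting the grid and gain consistently
  gt <- rec$ground_truth
  perm <- c(3, 1, 2, 5, 4, 8, 7, 6)
  grid_p <- source_grid(gt$source_positions[perm, ],
                        region_labels = gt$region_labels[perm])
  res_p <- analyze_recording(rec, "gamma", cfg, grid = grid_p,
                             gain = make_gain_matrix(
                               nrow(rec$channel_positions),
                               gt$source_positions,
                               rec$channel_positions,
                               seed = cfg$gain_seed)[, perm])
  key <- function(g, map = seq_len(g$n_sources)) {
    e <- g$edges
    a <- map[e$a]; b <- map[e$b]
    lo <- pmin(a, b); hi <- pmax(a, b)
    ord <- order(lo, hi)
    data.frame(lo = lo[ord], hi = hi[ord], R = round(e$R[ord], 8))
  }
  expect_equal(key(res_p$graph, map = perm), key(res$graph))
})
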