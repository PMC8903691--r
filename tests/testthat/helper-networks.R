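# Shared fixtures: the package's example study conditions plus an in-test
# brute-force graph-metric oracle kept independent of the implementation.

smoke_network <- function(...) example_network(...)
smoke_cohort_spec <- function(n_patients = 6, n_controls = 6, seed = 1, ...) {
  example_cohort_spec(n_patients = n_patients, n_controls = n_controls,
                      seed = seed, ...)
}
smoke_pipeline_config <- function(...) example_pipeline_config(...)

# Build a connectivity_graph directly from an edge table (bypassing the
# estimation stages) for graph-metric tests.
graph_from_edges <- function(n, a, b, R = rep(0.5, length(a)),
                             direction = rep("undirected", length(a))) {
  k <- length(a)
  edges <- data.frame(a = as.integer(a), b = as.integer(b), R = R,
                      Tp = rep(NA_real_, k), p = rep(NA_real_, k),
                      direction = direction,
                      sign = rep(NA_character_, k),
                      gc_ab = rep(NA_real_, k), gc_ba = rep(NA_real_, k),
                      stringsAsFactors = FALSE)
  g <- structure(list(n_sources = n, edges = edges, node_roles = NULL,
                      regions = rep("OTHER", n), band = NULL,
                      subject_id = "fix"),
                 class = "connectivity_graph")
  classify_edges_and_nodes(g)
}

# Brute-force graph metrics on an adjacency/weight matrix: direct
# enumeration, no shortest-path library.
oracle_metrics <- function(W) {
  n <- nrow(W)
  Am <- (W != 0) * 1
  deg <- rowSums(Am)
  strength <- rowSums(abs(W))
  L_vals <- c()
  for (i in seq_len(n)) {
    distv <- rep(Inf, n); distv[i] <- 0
    frontier <- i
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(Am[v, ] == 1 & distv > distv[v] + 1)
        distv[nb] <- distv[v] + 1
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    L_vals <- c(L_vals, distv[seq_len(n) > i & is.finite(distv)])
  }
  L <- if (length(L_vals)) mean(L_vals) else NA_real_
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(Am[i, ] == 1)
    k <- length(nb)
    if (k < 2) { cc[i] <- 0; next }
    links <- 0
    for (u in nb) for (v in nb) if (u < v && Am[u, v] == 1) links <- links + 1
    cc[i] <- 2 * links / (k * (k - 1))
  }
  list(degree = mean(deg), strength = mean(strength), L = L,
       clustering = mean(cc))
}

random_weight_matrix <- function(n, p_edge = 0.4) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) {
      w <- runif(1, -1, 1)
      W[i, j] <- W[j, i] <- w
    }
  }
  W
}

graph_from_weight_matrix <- function(W) {
  idx <- which(W != 0 & upper.tri(W), arr.ind = TRUE)
  graph_from_edges(nrow(W), idx[, 1], idx[, 2], R = W[idx])
}

# Exhaustive two-sided Fisher p by enumeration of all tables with the
# observed margins (probability-summation rule).
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(r1 + r2, c1))
  }, numeric(1))
  p_obs <- probs[tab[1, 1] - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
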