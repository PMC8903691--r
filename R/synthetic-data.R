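#' Spectral radius of the MVAR companion matrix
#'
#' An MVAR(p) process is stable (stationary) iff the spectral radius of its
#' companion matrix is below 1.
#'
#' @param coupling d x d x p array of lag coefficient matrices; entry
#'   `[i, j, k]` is the influence of source j at lag k on source i.
#' @return Largest eigenvalue modulus of the companion matrix.
#' @export
companion_spectral_radius <- function(coupling) {
  d <- dim(coupling)[1L]
  p <- dim(coupling)[3L]
  comp <- matrix(0, d * p, d * p)
  for (k in seq_len(p)) comp[seq_len(d), (k - 1L) * d + seq_len(d)] <- coupling[, , k]
  if (p > 1L) {
    comp[d + seq_len(d * (p - 1L)), seq_len(d * (p - 1L))] <- diag(d * (p - 1L))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Specify a directed source network (MVAR generative model)
#'
#' Describes the ground-truth source dynamics for simulation: a stable
#' multivariate autoregressive process whose innovations are band-shaped so
#' source power concentrates in the analysis band.
#'
#' @param coupling d x d x p array (or d x d matrix for p = 1) of MVAR lag
#'   coefficients; `[i, j, k]` couples source j -> source i at lag k.
#' @param noise_cov innovation covariance (symmetric positive definite);
#'   default identity.
#' @param band optional [band_definition()] used to shape source spectra.
#' @param region_labels one of PFC/TL/OCC/OTHER per source.
#' @param planted_edge optional `c(from, to)` source indices naming the
#'   coupling whose presence is manipulated between groups.
#' @return A `source_network_spec` object.
#' @export
source_network_spec <- function(coupling, noise_cov = NULL, band = NULL,
                                region_labels = NULL, planted_edge = NULL) {
  if (is.matrix(coupling)) coupling <- array(coupling, c(dim(coupling), 1L))
  d <- dim(coupling)[1L]
  stopifnot(dim(coupling)[2L] == d)
  if (is.null(noise_cov)) noise_cov <- diag(d)
  if (is.null(region_labels)) region_labels <- rep("OTHER", d)
  if (length(region_labels) != d) stop("region_labels length must equal n_sources")
  if (!isSymmetric(unname(noise_cov)) ||
      min(eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("noise_cov must be symmetric positive definite")
  }
  rho <- companion_spectral_radius(coupling)
  if (rho >= 1) {
    stop(sprintf("unstable MVAR spec: companion spectral radius %.4f >= 1", rho))
  }
  structure(
    list(n_sources = d, coupling = coupling, model_order = dim(coupling)[3L],
         noise_cov = noise_cov, band = band, region_labels = region_labels,
         planted_edge = planted_edge, spectral_radius = rho),
    class = "source_network_spec"
  )
}

#' Remove one directed coupling from a network spec
#'
#' Zeroes the `from -> to` coefficients at every lag and revalidates
#' stability.
#'
#' @param spec a [source_network_spec()].
#' @param from,to source indices.
#' @return A new `source_network_spec`.
#' @export
drop_coupling <- function(spec, from, to) {
  coupling <- spec$coupling
  coupling[to, from, ] <- 0
  source_network_spec(coupling, spec$noise_cov, spec$band,
                      spec$region_labels, spec$planted_edge)
}

# Per-subject network gain: scales the lag couplings and the instantaneous
# innovation cross-covariances together, so both the directed structure and
# the correlation weights (hence measured strength) track the factor. The
# planted pair is left at unit gain so that pattern detectability does not
# covary with the clinical anchor.
scale_network <- function(spec, factor, except = spec$planted_edge) {
  ncov <- spec$noise_cov
  off <- ncov - diag(diag(ncov))
  coupling <- spec$coupling * factor
  off <- off * factor
  if (!is.null(except)) {
    a <- except[1L]; b <- except[2L]
    coupling[b, a, ] <- spec$coupling[b, a, ]
    coupling[a, b, ] <- spec$coupling[a, b, ]
    off[a, b] <- spec$noise_cov[a, b]
    off[b, a] <- spec$noise_cov[b, a]
  }
  source_network_spec(coupling, diag(diag(ncov)) + off, spec$band,
                      spec$region_labels, spec$planted_edge)
}

#' Simulate a stable MVAR process
#'
#' Draws Gaussian innovations (band-shaped when the spec carries a band),
#' runs the autoregressive recursion, and discards a burn-in so the returned
#' segment is effectively stationary. Deterministic given `seed`.
#'
#' @param spec a [source_network_spec()].
#' @param n_samples samples to return (after burn-in).
#' @param seed RNG seed.
#' @param sfreq sampling rate, Hz; required when the spec has a band.
#' @param burn_in samples discarded at the start (>= 500).
#' @return sources x n_samples matrix.
#' @export
simulate_mvar <- function(spec, n_samples, seed, sfreq = NULL, burn_in = 500) {
  stopifnot(inherits(spec, "source_network_spec"))
  if (n_samples <= 10 * spec$model_order) {
    stop("n_samples must exceed 10 x model_order")
  }
  burn_in <- max(burn_in, 500L)
  d <- spec$n_sources
  n_tot <- n_samples + burn_in
  set.seed(seed)
  innov <- t(chol(spec$noise_cov)) %*%
    matrix(rnorm(d * n_tot), d, n_tot)
  if (!is.null(spec$band)) {
    # causal (forward-only) band shaping: a zero-phase filter here would
    # make the process depend on future innovations and corrupt the
    # directed (Granger) structure the simulation is meant to plant
    if (is.null(sfreq)) stop("sfreq required to band-shape innovations")
    bf <- butter_sos(4, c(spec$band$lo, spec$band$hi) / (sfreq / 2), "pass")
    innov <- sos_apply(bf$sections, innov)
  }
  x <- mvar_recurse(spec$coupling, innov)
  x[, burn_in + seq_len(n_samples), drop = FALSE]
}

#' Distance-kernel forward gain matrix
#'
#' A simplified linear forward model: the magnitude of the gain from source
#' j to channel i falls off with the inverse square of their distance,
#' modulated by a seeded orientation factor whose sign may flip across the
#' array (as real neuromagnetic field patterns do); columns are normalized
#' to unit norm. The orientation diversity keeps nearby sources' gain
#' columns from becoming collinear, which would make them inseparable for
#' any spatial filter.
#'
#' @param n_channels number of sensors.
#' @param source_positions sources x 3 matrix, meters.
#' @param channel_positions channels x 3 matrix, meters.
#' @param seed RNG seed for the orientation factors.
#' @return channels x sources gain matrix with unit-norm, full-rank columns.
#' @export
make_gain_matrix <- function(n_channels, source_positions, channel_positions,
                             seed = 1) {
  source_positions <- as.matrix(source_positions)
  channel_positions <- as.matrix(channel_positions)
  n_src <- nrow(source_positions)
  stopifnot(nrow(channel_positions) == n_channels, n_channels >= n_src)
  dd <- as.matrix(dist(source_positions))
  if (any(dd[upper.tri(dd)] < 1e-9)) {
    stop("duplicate source positions: forward model would be rank deficient")
  }
  set.seed(seed)
  gain <- matrix(0, n_channels, n_src)
  for (j in seq_len(n_src)) {
    dv <- sqrt(rowSums((channel_positions -
                          matrix(source_positions[j, ], n_channels, 3,
                                 byrow = TRUE))^2))
    orient <- 1 + rnorm(n_channels)
    gain[, j] <- orient / (dv^2 + 1e-4)
  }
  gain <- sweep(gain, 2L, sqrt(colSums(gain^2)), "/")
  if (qr(gain)$rank < n_src) stop("gain matrix is rank deficient")
  gain
}

#' Specify a two-group synthetic cohort
#'
#' @param n_patients,n_controls group sizes.
#' @param pattern_prevalence_patients,pattern_prevalence_controls probability
#'   that a subject's generating network contains the planted directed edge.
#' @param snr_db sensor signal-to-noise ratio in dB (signal variance over
#'   noise variance).
#' @param n_trials epochs per subject.
#' @param trial_samples samples per trial.
#' @param trigger_sample 1-based trigger index within each trial.
#' @param sfreq sampling rate, Hz.
#' @param n_channels number of sensors.
#' @param seed root RNG seed; all cohort randomness derives from it.
#' @param clinical_rho target Spearman correlation between
#'   `clinical_covariate` and the subject-level network gain factor
#'   (patients only); `NA` disables the construction.
#' @param clinical_covariate name of the tied covariate.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients = 24, n_controls = 24,
                        pattern_prevalence_patients = 19 / 24,
                        pattern_prevalence_controls = 8 / 24,
                        snr_db = 0, n_trials = 100,
                        trial_samples = 1000, trigger_sample = 100,
                        sfreq = 1000, n_channels = 50, seed = 1,
                        clinical_rho = NA, clinical_covariate = "ham_a") {
  stopifnot(pattern_prevalence_patients >= 0, pattern_prevalence_patients <= 1,
            pattern_prevalence_controls >= 0, pattern_prevalence_controls <= 1,
            n_trials >= 1, sfreq > 0)
  structure(
    list(n_patients = n_patients, n_controls = n_controls,
         pattern_prevalence_patients = pattern_prevalence_patients,
         pattern_prevalence_controls = pattern_prevalence_controls,
         snr_db = snr_db, n_trials = n_trials, trial_samples = trial_samples,
         trigger_sample = trigger_sample, sfreq = sfreq,
         n_channels = n_channels, seed = seed, clinical_rho = clinical_rho,
         clinical_covariate = clinical_covariate),
    class = "cohort_spec"
  )
}

# Spherical sensor cap + compact source cloud, deterministic given seed.
default_geometry <- function(n_channels, n_sources, seed) {
  set.seed(seed)
  u <- runif(n_channels, 0.3, 1)        # keep channels on the upper cap
  th <- runif(n_channels, 0, 2 * pi)
  chan <- 0.12 * cbind(sqrt(1 - u^2) * cos(th), sqrt(1 - u^2) * sin(th), u)
  src <- matrix(runif(n_sources * 3, -0.05, 0.05), n_sources, 3)
  # enforce a minimum separation so the forward model stays well conditioned
  repeat {
    dd <- as.matrix(dist(src))
    diag(dd) <- Inf
    bad <- which(apply(dd, 1L, min) < 0.02)
    if (!length(bad)) break
    src[bad, ] <- matrix(runif(length(bad) * 3, -0.05, 0.05), length(bad), 3)
  }
  list(channels = chan, sources = src)
}

# Marginals loosely matching a migraine clinic population; the tied covariate
# is re-generated through the copula afterwards.
draw_clinical <- function(group, n) {
  if (group == "patient") {
    list(history_years = pmax(0.5, rnorm(n, 11.2, 6.6)),
         freq_per_month = pmax(0.5, rnorm(n, 4.7, 4.4)),
         duration_hours = pmax(1, rnorm(n, 20.8, 17.7)),
         vas = pmin(10, pmax(1, rnorm(n, 7.4, 1.4))),
         ham_a = pmax(0, rnorm(n, 9.7, 4.6)),
         ham_d = pmax(0, rnorm(n, 10.3, 5.1)))
  } else {
    list(history_years = rep(NA_real_, n), freq_per_month = rep(NA_real_, n),
         duration_hours = rep(NA_real_, n), vas = rep(NA_real_, n),
         ham_a = pmax(0, rnorm(n, 1.0, 0.65)),
         ham_d = pmax(0, rnorm(n, 1.6, 0.78)))
  }
}

#' Gaussian-copula draw of a covariate with target Spearman correlation
#'
#' Produces values whose population Spearman correlation with `anchor` is
#' `rho_s`, with the marginal given by a monotone location/scale map of the
#' latent normal. Spearman correlation is invariant to the marginal choice.
#'
#' @param anchor numeric vector the covariate should rank-correlate with.
#' @param rho_s target Spearman correlation.
#' @param location,scale marginal parameters of the returned covariate.
#' @param floor lower truncation applied after the monotone map; ties at
#'   the floor slightly attenuate the realized correlation.
#' @return Numeric vector, same length as `anchor`.
#' @export
copula_covariate <- function(anchor, rho_s, location = 0, scale = 1,
                             floor = -Inf) {
  n <- length(anchor)
  r <- 2 * sin(pi * rho_s / 6)  # Pearson correlation of the latent normals
  z_a <- qnorm((rank(anchor, ties.method = "average") - 0.5) / n)
  z_c <- r * z_a + sqrt(1 - r^2) * rnorm(n)
  pmax(floor, location + scale * z_c)
}

#' Draw the per-subject ground-truth assignments of a cohort
#'
#' The Bernoulli edge-presence draws (at each group's prevalence) and the
#' per-subject background-network gain factors, seeded from the cohort
#' seed. Called by [generate_cohort()]; exposed so the assignment layer can
#' be audited without simulating signals.
#'
#' @param cohort a [cohort_spec()].
#' @return List with `group`, `edge_present`, `net_scale`.
#' @export
draw_cohort_assignments <- function(cohort) {
  n_tot <- cohort$n_patients + cohort$n_controls
  groups <- rep(c("patient", "control"),
                c(cohort$n_patients, cohort$n_controls))
  set.seed(derive_seed(cohort$seed, 11))
  prev <- ifelse(groups == "patient",
                 cohort$pattern_prevalence_patients,
                 cohort$pattern_prevalence_controls)
  list(group = groups,
       edge_present = runif(n_tot) < prev,
       net_scale = runif(n_tot, 0.4, 1.6))
}

#' Generate a synthetic two-group cohort of sensor recordings
#'
#' For every subject: decide (Bernoulli, at the group's prevalence) whether
#' the planted directed coupling is present, scale the network by a random
#' per-subject gain factor, simulate band-shaped MVAR sources, project them
#' to sensors through a distance-kernel gain matrix, and add white sensor
#' noise at the requested SNR. Patients' tied clinical covariate is drawn by
#' a Gaussian copula against the network gain factor. Fully deterministic
#' given the cohort seed.
#'
#' @param cohort a [cohort_spec()].
#' @param net_with network spec containing the planted edge (used when the
#'   Bernoulli draw is 1); must carry `planted_edge`.
#' @param net_without optional network for edge-absent subjects; default
#'   `drop_coupling(net_with, ...)`.
#' @param gain_seed seed of the forward-model orientation factors (shared
#'   with the reconstruction stage).
#' @return List of `recording` objects; ground truth (edge presence, network
#'   gain factor, gain matrix, source positions, region labels) is stored in
#'   each recording's `ground_truth` field.
#' @export
generate_cohort <- function(cohort, net_with, net_without = NULL,
                            gain_seed = 1) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(net_with, "source_network_spec"))
  if (is.null(net_with$planted_edge)) stop("net_with must carry planted_edge")
  if (!is.null(net_with$band) && net_with$band$hi * 2 >= cohort$sfreq) {
    stop("sfreq violates Nyquist for the network band")
  }
  if (is.null(net_without)) {
    net_without <- drop_coupling(net_with, net_with$planted_edge[1L],
                                 net_with$planted_edge[2L])
  }
  geom <- default_geometry(cohort$n_channels, net_with$n_sources,
                           derive_seed(cohort$seed, 7))
  gain <- make_gain_matrix(cohort$n_channels, geom$sources, geom$channels,
                           seed = gain_seed)

  asg <- draw_cohort_assignments(cohort)
  n_tot <- length(asg$group)
  groups <- asg$group
  edge_present <- asg$edge_present
  net_scale <- asg$net_scale

  clin_p <- draw_clinical("patient", cohort$n_patients)
  clin_c <- draw_clinical("control", cohort$n_controls)
  if (!is.na(cohort$clinical_rho)) {
    anchors <- net_scale[groups == "patient"]
    base <- clin_p[[cohort$clinical_covariate]]
    clin_p[[cohort$clinical_covariate]] <-
      copula_covariate(anchors, cohort$clinical_rho,
                       location = mean(base), scale = max(sd(base), 1),
                       floor = 0)
  }

  n_samp <- cohort$n_trials * cohort$trial_samples
  recs <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    net <- if (edge_present[i]) net_with else net_without
    net <- scale_network(net, net_scale[i])
    src <- simulate_mvar(net, n_samp, seed = derive_seed(cohort$seed, 100 + i),
                         sfreq = cohort$sfreq)
    sens <- gain %*% src
    sig_var <- mean(sens^2)
    noise_sd <- sqrt(sig_var / 10^(cohort$snr_db / 10))
    set.seed(derive_seed(cohort$seed, 5000 + i))
    sens <- sens + noise_sd * matrix(rnorm(length(sens)), nrow(sens))
    data <- array(sens, c(cohort$n_channels, cohort$trial_samples,
                          cohort$n_trials))
    gi <- if (groups[i] == "patient") i else i - cohort$n_patients
    clin <- lapply(if (groups[i] == "patient") clin_p else clin_c,
                   function(v) v[gi])
    recs[[i]] <- structure(
      list(data = data, contiguous_trials = TRUE, sfreq = cohort$sfreq,
           trigger_sample = cohort$trigger_sample,
           channel_positions = geom$channels, group = groups[i],
           clinical = clin,
           subject_id = sprintf("%s%02d", substr(groups[i], 1, 1), gi),
           ground_truth = list(edge_present = edge_present[i],
                               net_scale = net_scale[i],
                               planted_edge = net_with$planted_edge,
                               region_labels = net_with$region_labels,
                               source_positions = geom$sources,
                               snr_db = cohort$snr_db)),
      class = "recording")
  }
  recs
}

#' @export
print.recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<recording %s: %d ch x %d samples x %d trials @ %g Hz, %s>\n",
              x$subject_id, d[1], d[2], d[3], x$sfreq, x$group))
  invisible(x)
}

#' Example planted source network
#'
#' The reference 8-source network used by the package's validation studies:
#' a directed PFC -> TL coupling of 0.5 at lag 1 carries the planted
#' pattern, its instantaneous innovation correlation of 0.5 carries the
#' correlation edge, and three background pairs (one directed excitatory,
#' one directed inhibitory, one purely instantaneous) populate the rest of
#' the graph. Source spectra are shaped into the requested band.
#'
#' @param coupling planted PFC -> TL lag-1 coefficient (default 0.5).
#' @param d number of sources (>= 8 keeps the background structure).
#' @param band a [band_definition()] (default gamma).
#' @return A [source_network_spec()] with `planted_edge = c(1, 2)`.
#' @export
example_network <- function(coupling = 0.5, d = 8,
                            band = band_definition("gamma")) {
  stopifnot(d >= 8)
  A <- array(0, c(d, d, 2))
  diag(A[, , 1]) <- 0.3
  diag(A[, , 2]) <- 0.1
  A[2, 1, 1] <- coupling
  A[4, 3, 1] <- 0.35
  A[6, 5, 1] <- -0.3
  S <- diag(d)
  S[1, 2] <- S[2, 1] <- 0.5
  S[3, 4] <- S[4, 3] <- 0.4
  S[5, 6] <- S[6, 5] <- -0.4
  S[7, 8] <- S[8, 7] <- 0.45
  labels <- c("PFC", "TL", "OCC", rep("OTHER", d - 3))
  source_network_spec(A, noise_cov = S, band = band,
                      region_labels = labels, planted_edge = c(1, 2))
}

#' Example cohort specification at validation (smoke) scale
#'
#' Desk-scale study conditions used throughout the package's simulation
#' studies: 32 trials of 80 samples at 250 Hz over 32 channels at 10 dB
#' SNR. Group sizes and prevalences default to the two-group design the
#' pipeline is built around (24 + 24, 19/24 vs 8/24).
#'
#' @param n_patients,n_controls group sizes.
#' @param seed cohort seed.
#' @param ... overrides of any [cohort_spec()] argument.
#' @return A [cohort_spec()].
#' @export
example_cohort_spec <- function(n_patients = 24, n_controls = 24, seed = 1,
                                ...) {
  args <- list(n_patients = n_patients, n_controls = n_controls,
               snr_db = 10, n_trials = 32, trial_samples = 80,
               trigger_sample = 10, sfreq = 250, n_channels = 32,
               seed = seed)
  do.call(cohort_spec, utils::modifyList(args, list(...)))
}

#' Realized sensor signal-to-noise ratio
#'
#' Variance-ratio SNR audit used to check that generated recordings attain
#' the requested `snr_db`.
#'
#' @param signal,noise numeric arrays of equal size.
#' @return SNR in dB.
#' @export
snr_db_of <- function(signal, noise) {
  10 * log10(mean(signal^2) / mean(noise^2))
}
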