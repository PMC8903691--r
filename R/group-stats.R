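#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact p by summing the probabilities of all hypergeometric tables with
#' the observed margins whose point probability does not exceed the
#' observed table's (the probability-summation convention). A zero margin
#' returns p = 1 with a warning.
#'
#' @param table 2x2 matrix of nonnegative integer counts
#'   (group x pattern-present).
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("zero margin in 2x2 table; p = 1")
    return(1)
  }
  fisher.test(table)$p.value
}

#' Pooled two-sample t-test
#'
#' Student's (equal-variance) two-sample t with df = n_x + n_y - 2,
#' two-tailed by default.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param two_tailed two-sided p (default) or one-sided (greater).
#' @return List with `t`, `p`, `df`.
#' @export
ttest_two_sample <- function(x, y, two_tailed = TRUE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  tt <- t.test(x, y, var.equal = TRUE,
               alternative = if (two_tailed) "two.sided" else "greater")
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Bonferroni-corrected significance threshold
#'
#' Per-test threshold alpha / n. The two correction families used for the
#' network analyses are n = 5 (frequency bands; 0.05/5 = 0.01) and
#' n = 20 (5 bands x 4 graph parameters; 0.05/20 = 0.0025).
#'
#' @param alpha family-wise level (default 0.05).
#' @param n_tests number of tests in the family.
#' @return Per-test threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 1) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Benjamini-Hochberg FDR step-up rejections
#'
#' Sorts the p-values ascending and rejects all p(i) up to the largest i
#' with p(i) <= q * i / N.
#'
#' @param p_values numeric vector of p-values.
#' @param q FDR level (default 0.05).
#' @return Logical rejection flags in the input order.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  p.adjust(p_values, method = "BH") <= q
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of midranks; p from t = rho * sqrt((n-2)/(1-rho^2))
#' with n - 2 df (two-sided). For n <= 10 an exact permutation p is
#' available.
#'
#' @param x,y numeric vectors (n >= 4); NA pairs are dropped.
#' @param exact use the exact permutation distribution (n <= 10 only).
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n >= 4)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- cor(rx, ry)
  if (exact) {
    if (n > 10) stop("exact permutation p only for n <= 10")
    perms <- combinat_permutations(n)
    null_rho <- apply(perms, 1L, function(pr) cor(rx, ry[pr]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

combinat_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- combinat_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' Group-level analysis of a cohort's networks
#'
#' Per band: the directed pattern-prevalence 2x2 table with Fisher's exact
#' test; pooled t-tests of the four graph parameters between groups, with
#' both Bonferroni families (per-band and bands x parameters) and BH-FDR
#' flags; Spearman correlations of each clinical covariate against each
#' parameter within the patient group.
#'
#' @param metrics data frame from [graph_metrics()] rows plus columns
#'   `group` and `pattern` (logical pattern detection per subject).
#' @param clinical data frame of per-subject clinical covariates (patients
#'   may have columns controls lack); rows aligned with `metrics` subjects.
#' @param alpha family-wise level for the corrections (default 0.05).
#' @param n_bands,n_params correction family sizes (default 5 and 4).
#' @param fdr_q FDR level (default 0.05).
#' @return A `cohort_result`: `prevalence` (per band: table, fisher_p),
#'   `metric_tests` (per band x parameter: t, p_raw, thresholds, flags),
#'   `clinical_correlations`, and the thresholds used.
#' @export
run_group_analysis <- function(metrics, clinical = NULL, alpha = 0.05,
                               n_bands = 5, n_params = 4, fdr_q = 0.05) {
  stopifnot(all(c("group", "pattern", "band") %in% names(metrics)))
  params <- c("degree_D", "strength_S", "path_length_L", "clustering_C")
  thr_band <- bonferroni_threshold(alpha, n_bands)
  thr_full <- bonferroni_threshold(alpha, n_bands * n_params)

  prevalence <- lapply(split(metrics, metrics$band), function(m) {
    tab <- matrix(c(sum(m$group == "patient" & m$pattern),
                    sum(m$group == "patient" & !m$pattern),
                    sum(m$group == "control" & m$pattern),
                    sum(m$group == "control" & !m$pattern)),
                  2, 2, byrow = TRUE,
                  dimnames = list(c("patient", "control"),
                                  c("present", "absent")))
    list(table = tab, fisher_p = fisher_exact_2x2(tab))
  })

  tests <- do.call(rbind, lapply(split(metrics, metrics$band), function(m) {
    do.call(rbind, lapply(params, function(pm) {
      x <- m[[pm]][m$group == "patient"]
      y <- m[[pm]][m$group == "control"]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (length(x) < 2 || length(y) < 2) {
        return(data.frame(band = m$band[1], parameter = pm, t = NA_real_,
                          p_raw = NA_real_, stringsAsFactors = FALSE))
      }
      tt <- ttest_two_sample(x, y)
      data.frame(band = m$band[1], parameter = pm, t = tt$t, p_raw = tt$p,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(tests) <- NULL
  tests$sig_bonferroni_band <- tests$p_raw < thr_band
  tests$sig_bonferroni_full <- tests$p_raw < thr_full
  ok <- is.finite(tests$p_raw)
  tests$fdr_reject <- FALSE
  tests$fdr_reject[ok] <- fdr_bh(tests$p_raw[ok], fdr_q)

  clin_cor <- NULL
  if (!is.null(clinical)) {
    pat <- metrics$group == "patient"
    covs <- names(clinical)[vapply(clinical, is.numeric, logical(1))]
    clin_cor <- do.call(rbind, lapply(split(seq_len(nrow(metrics))[pat],
                                            metrics$band[pat]), function(idx) {
      do.call(rbind, lapply(covs, function(cv) {
        do.call(rbind, lapply(params, function(pm) {
          x <- clinical[[cv]][idx]; y <- metrics[[pm]][idx]
          keep <- is.finite(x) & is.finite(y)
          if (sum(keep) < 4) return(NULL)
          sp <- spearman_cor(x[keep], y[keep])
          data.frame(band = metrics$band[idx][1], covariate = cv,
                     parameter = pm, rho = sp$rho, p = sp$p, n = sp$n,
                     stringsAsFactors = FALSE)
        }))
      }))
    }))
    rownames(clin_cor) <- NULL
  }

  structure(list(prevalence = prevalence, metric_tests = tests,
                 clinical_correlations = clin_cor,
                 thresholds = list(alpha = alpha,
                                   bonferroni_band = thr_band,
                                   bonferroni_full = thr_full,
                                   fdr_q = fdr_q)),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort result>\n")
  for (b in names(x$prevalence)) {
    cat(sprintf("  band %s: Fisher p = %.4g\n", b, x$prevalence[[b]]$fisher_p))
  }
  sig <- x$metric_tests[which(x$metric_tests$sig_bonferroni_full), ]
  cat(sprintf("  %d/%d metric tests Bonferroni-significant (threshold %.4g)\n",
              nrow(sig), nrow(x$metric_tests), x$thresholds$bonferroni_full))
  invisible(x)
}
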