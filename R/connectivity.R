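#' Pairwise correlation matrix of virtual-sensor signals
#'
#' Pearson correlation between every source pair,
#' \deqn{R(X_a, X_b) = \frac{C(X_a, X_b)}{S_{X_a} S_{X_b}},}
#' the covariance of the two waveforms over their standard deviations.
#' Zero-variance sources are excluded (their rows/columns set to `NA`) with
#' a warning rather than propagating NaN.
#'
#' @param signals sources x samples matrix, or a `virtual_sensor_set`.
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `excluded` lists zero-variance source indices.
#' @export
pairwise_correlation <- function(signals) {
  if (inherits(signals, "virtual_sensor_set")) signals <- signals$signals
  signals <- as.matrix(signals)
  if (ncol(signals) < 3L) stop("need at least 3 samples per source")
  v <- apply(signals, 1L, var)
  excluded <- which(v < .Machine$double.eps)
  R <- matrix(NA_real_, nrow(signals), nrow(signals))
  ok <- setdiff(seq_len(nrow(signals)), excluded)
  R[ok, ok] <- cor(t(signals[ok, , drop = FALSE]))
  if (length(excluded)) {
    warning("excluding zero-variance source(s): ",
            paste(excluded, collapse = ", "))
  } else {
    diag(R) <- 1
  }
  attr(R, "excluded") <- excluded
  R
}

#' Threshold a correlation matrix by the t value of each correlation
#'
#' Each correlation is converted to a t statistic,
#' \deqn{T_p = R \sqrt{\frac{K - 2}{1 - R^2}},}
#' where K is the number of data points in the connection; a pair is
#' retained when the two-sided p-value of \eqn{T_p} under a t distribution
#' with K-2 degrees of freedom falls below `alpha`.
#'
#' @param R correlation matrix.
#' @param K number of data points per connection.
#' @param alpha retention threshold on the two-sided p-value (default 0.01).
#' @return List with `adjacency` (logical, FALSE diagonal), `Tp`, and `p`
#'   matrices.
#' @export
t_threshold <- function(R, K, alpha = 0.01) {
  if (K <= 2) stop("K must exceed 2")
  Tp <- R * sqrt((K - 2) / pmax(1 - R^2, .Machine$double.eps))
  p <- 2 * pt(-abs(Tp), df = K - 2)
  adjacency <- !is.na(p) & p < alpha
  diag(adjacency) <- FALSE
  list(adjacency = adjacency, Tp = Tp, p = p)
}

# Stacked least-squares fit of a VAR(p): response columns = predicted
# sources, design = intercept + p lags of the predictor sources. Lags never
# cross trial boundaries when trial_len is given.
var_design <- function(X, order, trial_len = NULL) {
  d <- nrow(X); n <- ncol(X)
  if (is.null(trial_len)) trial_len <- n
  stopifnot(n %% trial_len == 0)
  n_trials <- n %/% trial_len
  rows_y <- integer(0); lag_idx <- matrix(integer(0), 0, order)
  for (tr in seq_len(n_trials)) {
    off <- (tr - 1L) * trial_len
    t_use <- (order + 1L):trial_len
    rows_y <- c(rows_y, off + t_use)
    lag_idx <- rbind(lag_idx,
                     outer(off + t_use, seq_len(order), function(t, k) t - k))
  }
  Y <- t(X[, rows_y, drop = FALSE])
  Z <- matrix(1, length(rows_y), 1L + d * order)
  for (k in seq_len(order)) {
    Z[, 1L + (k - 1L) * d + seq_len(d)] <- t(X[, lag_idx[, k], drop = FALSE])
  }
  list(Y = Y, Z = Z, predictor_cols = function(sources) {
    c(1L, 1L + rep((seq_len(order) - 1L) * d, each = length(sources)) +
        rep(sources, order))
  })
}

var_fit_rss <- function(Z, Y) {
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) return(NULL)  # rank-deficient regression
  res <- qr.resid(qz, Y)
  list(rss = colSums(res^2), n = nrow(Z), k = ncol(Z), resid = res)
}

# BIC over the full joint model, common sample (worst-case order trimmed by
# using each candidate's own design; adequate for order selection here).
select_var_order <- function(X, order_max, trial_len = NULL) {
  d <- nrow(X)
  best <- 1L; best_bic <- Inf
  for (p in seq_len(order_max)) {
    des <- var_design(X, p, trial_len)
    fit <- var_fit_rss(des$Z, des$Y)
    if (is.null(fit)) next
    sigma <- crossprod(fit$resid) / fit$n
    ld <- determinant(sigma, logarithm = TRUE)$modulus
    bic <- fit$n * as.numeric(ld) + log(fit$n) * (d^2 * p + d)
    if (bic < best_bic) { best_bic <- bic; best <- p }
  }
  best
}

#' Granger-causal direction of retained connections
#'
#' Fits an MVAR model by least squares (order chosen by BIC up to
#' `model_order_max`) and computes, for every retained pair, the
#' log-variance-ratio Granger statistic
#' \deqn{GC(a \to b) = \ln \frac{\hat\sigma^2_{b | \mathrm{reduced}}}
#' {\hat\sigma^2_{b | \mathrm{full}}},}
#' the reduced model omitting source a's lags. Direction a -> b is assigned
#' when GC(a -> b) is significant (F-test at `alpha`) and the reverse is
#' not; both significant gives "bidirectional", neither "undirected".
#' With `conditional = TRUE` (and at most `gc_max_system` sources) the full
#' model conditions on all other sources; otherwise each pair is modeled
#' bivariately.
#'
#' @param signals sources x samples matrix.
#' @param pairs two-column matrix of retained source-index pairs (a, b).
#' @param model_order_max maximum MVAR order; default covers 20 ms of lags
#'   at `sfreq` (or 5 lags when `sfreq` is `NULL`).
#' @param conditional condition each pair's model on the remaining sources.
#' @param alpha F-test significance level for direction (default 0.05).
#' @param trial_len samples per trial when `signals` concatenates equal
#'   trials (lags then never cross trial boundaries).
#' @param sfreq sampling rate, Hz (sets the default order bound).
#' @param gc_max_system largest system size for conditional GC; above it the
#'   computation downgrades to pairwise with a message.
#' @return Data frame: a, b, gc_ab, gc_ba, p_ab, p_ba, direction, order.
#' @export
granger_direction <- function(signals, pairs, model_order_max = NULL,
                              conditional = TRUE, alpha = 0.05,
                              trial_len = NULL, sfreq = NULL,
                              gc_max_system = 20) {
  if (inherits(signals, "virtual_sensor_set")) signals <- signals$signals
  signals <- as.matrix(signals)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  d <- nrow(signals)
  if (is.null(model_order_max)) {
    model_order_max <- if (is.null(sfreq)) 5L else max(1L, round(0.020 * sfreq))
  }
  if (conditional && d > gc_max_system) {
    message("system size ", d, " exceeds gc_max_system = ", gc_max_system,
            "; downgrading to pairwise GC")
    conditional <- FALSE
  }
  empty <- data.frame(a = integer(0), b = integer(0), gc_ab = numeric(0),
                      gc_ba = numeric(0), p_ab = numeric(0),
                      p_ba = numeric(0), direction = character(0),
                      order = integer(0), stringsAsFactors = FALSE)
  if (!nrow(pairs)) return(empty)

  # Fits a subsystem once and answers GC queries between its columns;
  # reduced fits (one per omitted source) are cached and shared across
  # pairs, which makes the conditional mode a single full-model fit plus at
  # most d reduced fits regardless of the number of retained pairs.
  gc_system <- function(X) {
    dX <- nrow(X)
    p <- select_var_order(X, model_order_max, trial_len)
    if (ncol(X) < 10 * p * dX) {
      stop("too few samples for MVAR order ", p, " on ", dX, " sources")
    }
    des <- var_design(X, p, trial_len)
    full <- var_fit_rss(des$Z, des$Y)
    if (is.null(full)) stop("rank-deficient regression in full model")
    reduced_cache <- vector("list", dX)
    reduced_rss <- function(omit) {
      if (is.null(reduced_cache[[omit]])) {
        keep <- des$predictor_cols(setdiff(seq_len(dX), omit))
        fit <- var_fit_rss(des$Z[, keep, drop = FALSE], des$Y)
        if (is.null(fit)) stop("rank-deficient regression in reduced model")
        reduced_cache[[omit]] <<- fit$rss
      }
      reduced_cache[[omit]]
    }
    one_dir <- function(from, to) {
      rss_r <- reduced_rss(from)[to]
      gc <- log(rss_r / max(full$rss[to], .Machine$double.xmin))
      Fstat <- ((rss_r - full$rss[to]) / p) / (full$rss[to] / (full$n - full$k))
      pval <- pf(Fstat, p, full$n - full$k, lower.tail = FALSE)
      c(gc = max(gc, 0), p = pval)
    }
    list(one_dir = one_dir, order = p)
  }
  gc_pair <- function(sys, ia, ib) {
    list(ab = sys$one_dir(ia, ib), ba = sys$one_dir(ib, ia),
         order = sys$order)
  }

  cond_sys <- if (conditional) tryCatch(gc_system(signals),
                                        error = function(e) NULL) else NULL
  out <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1L]; b <- pairs[r, 2L]
    res <- tryCatch({
      if (conditional) {
        if (is.null(cond_sys)) NULL else gc_pair(cond_sys, a, b)
      } else {
        gc_pair(gc_system(signals[c(a, b), , drop = FALSE]), 1L, 2L)
      }
    }, error = function(e) NULL)
    if (is.null(res)) {
      out[[r]] <- data.frame(a = a, b = b, gc_ab = NA_real_, gc_ba = NA_real_,
                             p_ab = NA_real_, p_ba = NA_real_,
                             direction = "undirected", order = NA_integer_,
                             stringsAsFactors = FALSE)
      next
    }
    sig_ab <- res$ab[["p"]] < alpha
    sig_ba <- res$ba[["p"]] < alpha
    direction <- if (sig_ab && sig_ba) "bidirectional"
    else if (sig_ab) "a->b"
    else if (sig_ba) "b->a"
    else "undirected"
    out[[r]] <- data.frame(a = a, b = b,
                           gc_ab = res$ab[["gc"]], gc_ba = res$ba[["gc"]],
                           p_ab = res$ab[["p"]], p_ba = res$ba[["p"]],
                           direction = direction, order = res$order,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Build the signed directed connectivity graph for one subject
#'
#' Runs correlation (Eq. R), t-value thresholding, and Granger direction on
#' a virtual-sensor set, returning a `connectivity_graph`.
#'
#' @param vs a `virtual_sensor_set` (typically from [reconstruct_windows()]).
#' @param alpha edge-retention threshold on the correlation p-value.
#' @param signal_mode `"averaged"`: correlate/direct the trial-averaged
#'   window (K = window samples); `"concatenated"`: use the concatenated
#'   per-trial windows (K = total samples, trial-aware lags).
#' @param gc_alpha significance level of the direction F-tests.
#' @param ... passed to [granger_direction()].
#' @return A `connectivity_graph`: `n_sources`, `edges` data frame
#'   (a, b, R, Tp, p, direction, sign, gc_ab, gc_ba), `node_roles`,
#'   `regions`, `band`, `subject_id`.
#' @export
build_connectivity_graph <- function(vs, alpha = 0.01,
                                     signal_mode = c("averaged", "concatenated"),
                                     gc_alpha = 0.05, ...) {
  stopifnot(inherits(vs, "virtual_sensor_set"))
  signal_mode <- match.arg(signal_mode)
  wl <- attr(vs, "window_len")
  if (signal_mode == "averaged") {
    if (is.null(wl)) {
      signals <- vs$signals
    } else {
      n_tr <- ncol(vs$signals) %/% wl
      signals <- Reduce(`+`, lapply(seq_len(n_tr), function(tr) {
        vs$signals[, (tr - 1L) * wl + seq_len(wl), drop = FALSE]
      })) / n_tr
    }
    trial_len <- NULL
  } else {
    signals <- vs$signals
    trial_len <- wl
  }
  R <- pairwise_correlation(signals)
  th <- t_threshold(R, K = ncol(signals), alpha = alpha)
  pairs <- which(th$adjacency & upper.tri(th$adjacency), arr.ind = TRUE)
  gc <- granger_direction(signals, pairs, alpha = gc_alpha,
                          trial_len = trial_len, ...)
  edges <- if (nrow(gc)) {
    data.frame(a = gc$a, b = gc$b,
               R = R[cbind(gc$a, gc$b)], Tp = th$Tp[cbind(gc$a, gc$b)],
               p = th$p[cbind(gc$a, gc$b)],
               direction = gc$direction, sign = NA_character_,
               gc_ab = gc$gc_ab, gc_ba = gc$gc_ba,
               stringsAsFactors = FALSE)
  } else {
    data.frame(a = integer(0), b = integer(0), R = numeric(0),
               Tp = numeric(0), p = numeric(0), direction = character(0),
               sign = character(0), gc_ab = numeric(0), gc_ba = numeric(0),
               stringsAsFactors = FALSE)
  }
  graph <- structure(
    list(n_sources = nrow(signals), edges = edges,
         node_roles = NULL, regions = vs$grid$region_labels,
         band = vs$band, subject_id = vs$subject_id),
    class = "connectivity_graph")
  classify_edges_and_nodes(graph)
}

#' Annotate edge signs and node roles
#'
#' Edges with positive correlation are excitatory, negative inhibitory. A
#' node is a `driver` when its out-degree over directed edges exceeds its
#' in-degree, `driven` when reversed, `mixed` when equal and the node has at
#' least one edge, and `isolated` otherwise. Bidirectional edges count in
#' both directions.
#'
#' @param graph a `connectivity_graph`.
#' @return The graph with `edges$sign` and `node_roles` filled in.
#' @export
classify_edges_and_nodes <- function(graph) {
  stopifnot(inherits(graph, "connectivity_graph"))
  e <- graph$edges
  e$sign <- ifelse(e$R > 0, "excitatory", "inhibitory")
  out_deg <- in_deg <- any_edge <- rep(0L, graph$n_sources)
  for (r in seq_len(nrow(e))) {
    a <- e$a[r]; b <- e$b[r]
    any_edge[c(a, b)] <- 1L
    if (e$direction[r] %in% c("a->b", "bidirectional")) {
      out_deg[a] <- out_deg[a] + 1L; in_deg[b] <- in_deg[b] + 1L
    }
    if (e$direction[r] %in% c("b->a", "bidirectional")) {
      out_deg[b] <- out_deg[b] + 1L; in_deg[a] <- in_deg[a] + 1L
    }
  }
  roles <- ifelse(any_edge == 0L, "isolated",
                  ifelse(out_deg > in_deg, "driver",
                         ifelse(in_deg > out_deg, "driven", "mixed")))
  graph$edges <- e
  graph$node_roles <- roles
  graph
}

#' Detect a directed region-to-region connection pattern
#'
#' TRUE when at least `min_edges` directed edges run from a node labelled
#' `src_region` to a node labelled `dst_region` (bidirectional edges count
#' in both directions; undirected edges do not count).
#'
#' @param graph a `connectivity_graph` with region labels.
#' @param src_region,dst_region region labels (e.g. "PFC", "TL").
#' @param min_edges minimum number of qualifying edges (default 1).
#' @return Logical.
#' @export
detect_pattern <- function(graph, src_region = "PFC", dst_region = "TL",
                           min_edges = 1) {
  stopifnot(inherits(graph, "connectivity_graph"))
  if (is.null(graph$regions)) stop("graph carries no region labels")
  e <- graph$edges
  if (!nrow(e)) return(FALSE)
  reg <- graph$regions
  fwd <- e$direction %in% c("a->b", "bidirectional") &
    reg[e$a] == src_region & reg[e$b] == dst_region
  rev <- e$direction %in% c("b->a", "bidirectional") &
    reg[e$b] == src_region & reg[e$a] == dst_region
  sum(fwd) + sum(rev) >= min_edges
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("<connectivity graph %s: %d sources, %d edges%s>\n",
              if (is.null(x$subject_id)) "" else x$subject_id,
              x$n_sources, nrow(x$edges),
              if (!is.null(x$band)) paste0(", band ", x$band$name) else ""))
  invisible(x)
}
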