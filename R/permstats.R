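## Permutation inference ----------------------------------------------------
##
## Three nonparametric tests share the machinery here:
##   * a label-switch permutation test for paired condition comparisons of
##     a scalar statistic (the scalp-level ITPC comparison);
##   * a ROI-level "global statistic" permutation: per-ROI paired t-tests,
##     sum of suprathreshold t-values as a global statistic, null built by
##     label switching (multiple-comparison correction across ROIs);
##   * a spatio-temporal cluster permutation test for unit x time data
##     (the TRF condition comparison).
## All p-values use the add-one rule p = (1 + #{null >= obs}) / (1 + n_perm)
## with ties counted as ">= observed" (conservative), so p >= 1/(n_perm+1).

## Sign matrices encoding label switches. "half_swap" switches condition
## labels in a random subset of exactly floor(n/2) participants per
## permutation (the literal reading of the published scheme);
## "bernoulli" flips each participant independently (the FieldTrip
## convention), which is the scheme used for cluster nulls.
perm_sign_matrix <- function(n, n_perm, scheme = c("half_swap", "bernoulli")) {
  scheme <- match.arg(scheme)
  if (scheme == "half_swap") {
    k <- n %/% 2
    t(vapply(seq_len(n_perm), function(i) {
      s <- rep(1, n); s[sample.int(n, k)] <- -1; s
    }, numeric(n)))
  } else {
    matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n_perm, n)
  }
}

## Vectorized paired t for sign-flipped difference vectors.
## diffs: n x K matrix; signs: n_perm x n. Returns n_perm x K t-values
## (0/0 -> 0 convention).
perm_t_values <- function(diffs, signs) {
  diffs <- as.matrix(diffs)
  n <- nrow(diffs)
  means <- signs %*% diffs / n
  ss <- matrix(colSums(diffs^2), nrow(signs), ncol(diffs), byrow = TRUE)
  v <- (ss - n * means^2) / (n - 1)
  v[v < 1e-14 * pmax(ss, 1)] <- 0
  t <- means / sqrt(v / n)
  t[is.nan(t)] <- 0 # 0/0: all differences exactly zero
  t
}

add_one_p <- function(null, observed, tail = c("one_sided_greater", "two_sided")) {
  tail <- match.arg(tail)
  if (tail == "two_sided") {
    null <- abs(null); observed <- abs(observed)
  }
  (1 + sum(null >= observed - 1e-12)) / (1 + length(null))
}

#' Paired condition permutation test (label switch)
#'
#' Tests a per-participant paired statistic (e.g. channel-averaged 1 Hz
#' ITPC) between two conditions. The observed paired t is compared to a
#' null distribution built by switching condition labels in half of the
#' participants (a random subset of exactly `floor(n/2)` per permutation)
#' and recomputing the paired t.
#'
#' @param values_a,values_b per-participant statistic in conditions A and B
#'   (same participants, same order).
#' @param n_perm number of permutations (default 1000).
#' @param tail `"one_sided_greater"` (A > B, the default: the direction of
#'   the a-priori prediction) or `"two_sided"`.
#' @param seed integer seed.
#' @param scheme `"half_swap"` (default) or `"bernoulli"` label switching.
#' @return object of class `perm_test` with `observed_stat`,
#'   `null_distribution`, `p`, `n_perm`, `tail`, `seed`.
#' @export
condition_permutation_test <- function(values_a, values_b, n_perm = 1000,
                                       tail = c("one_sided_greater", "two_sided"),
                                       seed = 1,
                                       scheme = c("half_swap", "bernoulli")) {
  tail <- match.arg(tail); scheme <- match.arg(scheme)
  stop_if_not(length(values_a) == length(values_b),
              "conditions must have the same participants")
  n <- length(values_a)
  stop_if_not(n >= 4, "need at least 4 participants (got %d): null too coarse", n)
  d <- values_a - values_b
  observed <- t_stat(d)
  null <- with_seed(seed, {
    signs <- perm_sign_matrix(n, n_perm, scheme)
    as.numeric(perm_t_values(matrix(d, ncol = 1), signs))
  })
  structure(list(observed_stat = observed, null_distribution = null,
                 p = add_one_p(null, observed, tail),
                 n_perm = n_perm, tail = tail, seed = seed, scheme = scheme),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test (%s, %d perms): stat = %.3f, p = %.4g\n",
              x$tail, x$n_perm, x$observed_stat, x$p))
  invisible(x)
}

#' ROI-level global-statistic permutation test
#'
#' Runs a paired t-test in every ROI; ROIs passing an uncorrected
#' threshold (`threshold_p`, two-sided) contribute their t-value to a
#' global statistic (signed sum by default, or sum of |t|). The null is
#' built with the half-swap label-switching scheme; the pattern is
#' significant if the observed global statistic falls in the top 5% of the
#' null. Run separately per hemisphere by the caller.
#'
#' @param values_a,values_b participants x ROIs matrices.
#' @param threshold_p uncorrected per-ROI threshold (default 0.05).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param statistic `"signed"` (default; sum of t with sign, one-sided
#'   against the null) or `"absolute"` (sum of |t|).
#' @return object of class `roi_perm_test`: per-ROI `t` and uncorrected
#'   `p`, `suprathreshold` ROI indices, `global_stat`, `global_p`,
#'   `null_distribution`.
#' @export
roi_global_permutation <- function(values_a, values_b, threshold_p = 0.05,
                                   n_perm = 1000, seed = 1,
                                   statistic = c("signed", "absolute")) {
  statistic <- match.arg(statistic)
  values_a <- as.matrix(values_a); values_b <- as.matrix(values_b)
  stop_if_not(all(dim(values_a) == dim(values_b)),
              "condition matrices must have identical dimensions")
  stop_if_not(ncol(values_a) >= 2, "need at least 2 ROIs")
  n <- nrow(values_a)
  stop_if_not(n >= 4, "need at least 4 participants")
  diffs <- values_a - values_b
  t_crit <- stats::qt(1 - threshold_p / 2, df = n - 1)
  global_of <- function(tv) {
    sup <- abs(tv) > t_crit
    if (!any(sup)) return(0)
    if (statistic == "signed") sum(tv[sup]) else sum(abs(tv[sup]))
  }
  t_obs <- apply(diffs, 2, t_stat)
  p_obs <- 2 * stats::pt(-abs(t_obs), df = n - 1)
  sup_obs <- which(abs(t_obs) > t_crit)
  g_obs <- global_of(t_obs)
  null <- with_seed(seed, {
    signs <- perm_sign_matrix(n, n_perm, "half_swap")
    tm <- perm_t_values(diffs, signs)
    apply(tm, 1, global_of)
  })
  structure(list(t = t_obs, p_uncorrected = p_obs,
                 suprathreshold = sup_obs,
                 global_stat = g_obs,
                 global_p = add_one_p(null, g_obs, "one_sided_greater"),
                 null_distribution = null, threshold_p = threshold_p,
                 n_perm = n_perm, seed = seed, statistic = statistic),
            class = "roi_perm_test")
}

#' @export
print.roi_perm_test <- function(x, ...) {
  cat(sprintf("ROI global permutation: %d/%d ROIs suprathreshold, global stat = %.2f, p = %.4g\n",
              length(x$suprathreshold), length(x$t), x$global_stat, x$global_p))
  invisible(x)
}

## Connected components of suprathreshold (unit, bin) points.
## mask: units x bins logical; adjacency: units x units logical (spatial
## neighbors); temporal adjacency is |bin - bin'| == 1 within a unit.
## Returns a list of integer matrices with columns (unit, bin).
find_clusters <- function(mask, adjacency) {
  U <- nrow(mask); B <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  nb_units <- lapply(seq_len(U), function(u) which(adjacency[u, ]))
  visited <- logical(U * B)
  in_mask <- logical(U * B); in_mask[idx] <- TRUE
  clusters <- list()
  for (s in idx) {
    if (visited[s]) next
    queue <- s; visited[s] <- TRUE; members <- integer(0)
    while (length(queue)) {
      node <- queue[[1]]; queue <- queue[-1]
      members <- c(members, node)
      u <- (node - 1L) %% U + 1L
      b <- (node - 1L) %/% U + 1L
      cand <- integer(0)
      if (b > 1L) cand <- c(cand, node - U)
      if (b < B) cand <- c(cand, node + U)
      if (length(nb_units[[u]]))
        cand <- c(cand, (b - 1L) * U + nb_units[[u]])
      cand <- cand[in_mask[cand] & !visited[cand]]
      visited[cand] <- TRUE
      queue <- c(queue, cand)
    }
    clusters[[length(clusters) + 1L]] <-
      cbind(unit = (members - 1L) %% U + 1L, bin = (members - 1L) %/% U + 1L)
  }
  clusters
}

#' Spatio-temporal cluster permutation test
#'
#' First-level paired t-tests at every (unit, time-bin) point; points
#' exceeding the two-sided `threshold_p` critical t are grouped into
#' spatio-temporally connected clusters (adjacent time bins within a unit;
#' spatially adjacent units within a bin; positive and negative points
#' cluster separately). Cluster mass is the sum of t-values. The null is
#' the maximum absolute cluster mass over permutations of condition-label
#' sign flips; each observed cluster gets an add-one corrected p.
#'
#' @param data_a,data_b participants x units x bins arrays.
#' @param adjacency units x units logical/0-1 matrix of spatial neighbors
#'   (diagonal ignored). Units with no neighbors are allowed (a warning is
#'   issued) and cluster only along time.
#' @param threshold_p first-level threshold (default 0.05).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return object of class `cluster_test`: `clusters` (list with `members`
#'   (unit, bin) matrix, `mass`, `corrected_p`; sorted by decreasing
#'   |mass|), `t` (units x bins observed t), `null_distribution`,
#'   `threshold_p`, `n_perm`, `seed`.
#' @export
cluster_permutation <- function(data_a, data_b, adjacency, threshold_p = 0.05,
                                n_perm = 1000, seed = 1) {
  stop_if_not(length(dim(data_a)) == 3 && all(dim(data_a) == dim(data_b)),
              "`data_a` and `data_b` must be participants x units x bins arrays of equal size")
  n <- dim(data_a)[1]; U <- dim(data_a)[2]; B <- dim(data_a)[3]
  stop_if_not(n >= 4, "need at least 4 participants")
  stop_if_not(B >= 2, "need at least 2 time bins")
  adjacency <- as.matrix(adjacency)
  stop_if_not(all(dim(adjacency) == c(U, U)), "`adjacency` must be units x units")
  adjacency <- adjacency != 0
  diag(adjacency) <- FALSE
  if (any(rowSums(adjacency) == 0) && U > 1)
    warning("adjacency has units with no spatial neighbors; they cluster only along time")
  diffs <- matrix(data_a - data_b, n, U * B) # participants x (unit,bin)
  t_crit <- stats::qt(1 - threshold_p / 2, df = n - 1)

  masses_of <- function(tv) {
    tm <- matrix(tv, U, B)
    out <- list()
    for (sgn in c(1, -1)) {
      cl <- find_clusters(sgn * tm > t_crit, adjacency)
      for (ci in cl) {
        out[[length(out) + 1L]] <-
          list(members = ci, mass = sum(tm[ci[, "unit"] + (ci[, "bin"] - 1L) * U]))
      }
    }
    out
  }

  t_obs <- as.numeric(perm_t_values(diffs, matrix(1, 1, n)))
  obs_clusters <- masses_of(t_obs)
  null <- with_seed(seed, {
    signs <- perm_sign_matrix(n, n_perm, "bernoulli")
    tm <- perm_t_values(diffs, signs)
    vapply(seq_len(n_perm), function(i) {
      cl <- masses_of(tm[i, ])
      if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, 0, "mass")))
    }, 0)
  })
  if (length(obs_clusters)) {
    ord <- order(-abs(vapply(obs_clusters, `[[`, 0, "mass")))
    obs_clusters <- obs_clusters[ord]
    for (i in seq_along(obs_clusters))
      obs_clusters[[i]]$corrected_p <-
        add_one_p(null, abs(obs_clusters[[i]]$mass), "one_sided_greater")
  }
  structure(list(clusters = obs_clusters, t = matrix(t_obs, U, B),
                 null_distribution = null, threshold_p = threshold_p,
                 n_perm = n_perm, seed = seed),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  if (!length(x$clusters)) {
    cat("cluster permutation: no suprathreshold clusters\n")
  } else {
    cat(sprintf("cluster permutation: %d cluster(s)\n", length(x$clusters)))
    for (cl in x$clusters)
      cat(sprintf("  mass = %.2f over %d points, corrected p = %.4g\n",
                  cl$mass, nrow(cl$members), cl$corrected_p))
  }
  invisible(x)
}

#' Windowed ROI-level TRF comparison
#'
#' Averages TRFs in consecutive 20 ms windows inside the 70-180 ms
#' analysis window (trailing partial windows are dropped, leaving 5 full
#' windows at the defaults), then runs the spatio-temporal cluster
#' permutation over ROIs x windows.
#'
#' @param trf_a,trf_b participants x ROIs x lags arrays.
#' @param lag_times lag axis in seconds (length = 3rd dimension).
#' @param window_len window length in seconds (default 0.020).
#' @param analysis_window analysis window in seconds (default c(0.070, 0.180)).
#' @param adjacency ROI adjacency matrix; default: all ROIs mutually
#'   adjacent (a clique).
#' @param n_perm,seed,threshold_p passed to [cluster_permutation()].
#' @return a `cluster_test` whose bins are the 20 ms windows; carries a
#'   `windows` attribute with the window start/end times.
#' @export
windowed_roi_trf_test <- function(trf_a, trf_b, lag_times,
                                  window_len = 0.020,
                                  analysis_window = c(0.070, 0.180),
                                  adjacency = NULL,
                                  threshold_p = 0.05, n_perm = 1000, seed = 1) {
  stop_if_not(length(dim(trf_a)) == 3 && all(dim(trf_a) == dim(trf_b)),
              "TRF arrays must be participants x ROIs x lags of equal size")
  stop_if_not(length(lag_times) == dim(trf_a)[3],
              "`lag_times` must match the lag dimension")
  dt <- stats::median(diff(lag_times))
  stop_if_not(abs(window_len / dt - round(window_len / dt)) < 1e-6,
              "window length %g s is misaligned with the TRF sampling step %g s",
              window_len, dt)
  stop_if_not(min(lag_times) <= analysis_window[1] + 1e-9 &&
                max(lag_times) >= analysis_window[2] - 1e-9,
              "TRF lag axis does not cover the analysis window")
  starts <- seq(analysis_window[1], analysis_window[2] - window_len + 1e-9,
                by = window_len)
  n_win <- length(starts)
  stop_if_not(n_win >= 1, "analysis window shorter than one window")
  U <- dim(trf_a)[2]; n <- dim(trf_a)[1]
  avg_windows <- function(x) {
    out <- array(0, c(n, U, n_win))
    for (w in seq_len(n_win)) {
      sel <- which(lag_times >= starts[w] - 1e-9 &
                     lag_times < starts[w] + window_len - 1e-9)
      stop_if_not(length(sel) > 0, "window at %g s contains no TRF samples", starts[w])
      out[, , w] <- apply(x[, , sel, drop = FALSE], c(1, 2), mean)
    }
    out
  }
  if (is.null(adjacency)) {
    adjacency <- matrix(TRUE, U, U); diag(adjacency) <- FALSE
  }
  res <- cluster_permutation(avg_windows(trf_a), avg_windows(trf_b), adjacency,
                             threshold_p = threshold_p, n_perm = n_perm,
                             seed = seed)
  attr(res, "windows") <- data.frame(t_start = starts, t_end = starts + window_len)
  res
}

#' Rook-adjacency matrix for a 2-D channel grid
#'
#' @param nrow,ncol grid dimensions (channels are numbered column-major).
#' @return logical adjacency matrix.
#' @export
grid_adjacency <- function(nrow, ncol) {
  U <- nrow * ncol
  adj <- matrix(FALSE, U, U)
  for (r in seq_len(nrow)) for (c in seq_len(ncol)) {
    i <- (c - 1) * nrow + r
    if (r < nrow) { adj[i, i + 1] <- TRUE; adj[i + 1, i] <- TRUE }
    if (c < ncol) { adj[i, i + nrow] <- TRUE; adj[i + nrow, i] <- TRUE }
  }
  adj
}
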