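## Temporal response functions by normalized reverse correlation -------------
##
## The TRF is the linear kernel k(lag) mapping the attended-speech envelope
## s(t) to the neural response r(t): r(t) ~ sum_l k(l) s(t - l). It is
## estimated from the lag-domain normal equations: the stimulus-response
## cross-covariance divided by the stimulus autocovariance, with the
## autocovariance pseudo-inverted after discarding trailing eigencomponents
## ("tolerance": the fraction of eigenvalue mass retained) and kernel
## coefficients zeroed when they are unstable across jackknife resamples
## ("sparseness": the minimum |mean|/SE ratio a coefficient must reach).
## Both hyperparameters are selected by leave-one-trial-out cross-validation
## on predictive power (Pearson r between predicted and held-out response).

#' TRF hyperparameters
#'
#' @param tolerance fraction of stimulus-autocovariance eigenvalue mass
#'   retained when pseudo-inverting, in (0, 1]. 1 keeps everything above
#'   numerical rank.
#' @param sparseness jackknife-stability threshold (>= 0): kernel
#'   coefficients whose |jackknife mean| / jackknife SE falls below this
#'   value are zeroed. 0 disables thresholding.
#' @return object of class `trf_hyperparams`.
#' @export
trf_hyperparams <- function(tolerance = 1, sparseness = 0) {
  stop_if_not(is_scalar_num(tolerance) && tolerance > 0 && tolerance <= 1,
              "`tolerance` must be in (0, 1]")
  stop_if_not(is_scalar_num(sparseness) && sparseness >= 0,
              "`sparseness` must be >= 0")
  structure(list(tolerance = tolerance, sparseness = sparseness),
            class = "trf_hyperparams")
}

## ---- internal workspace ---------------------------------------------------

## Per-trial lagged design matrix: X[t, l] = s(t - lag_l), zeros outside.
lagged_matrix <- function(env, lag_samples) {
  T <- length(env)
  L <- length(lag_samples)
  X <- matrix(0, T, L)
  for (l in seq_len(L)) {
    s <- lag_samples[l]
    if (s >= 0) {
      if (s < T) X[(s + 1):T, l] <- env[1:(T - s)]
    } else {
      if (-s < T) X[1:(T + s), l] <- env[(1 - s):T]
    }
  }
  X
}

## Precomputed moments for fast fold / permutation arithmetic.
## envelopes: list of numeric; responses: list of channels x T matrices.
trf_workspace <- function(envelopes, responses, sample_rate, lags_ms) {
  stop_if_not(length(envelopes) == length(responses) && length(envelopes) >= 1,
              "`envelopes` and `responses` must be matched non-empty lists")
  responses <- lapply(responses, function(r) {
    if (is.null(dim(r))) matrix(r, nrow = 1) else as.matrix(r)
  })
  N <- length(envelopes)
  for (i in seq_len(N)) {
    stop_if_not(length(envelopes[[i]]) == ncol(responses[[i]]),
                "trial %d: envelope and response lengths differ", i)
    stop_if_not(stats::sd(envelopes[[i]]) > 0,
                "trial %d: constant (zero-variance) envelope", i)
  }
  lag_samples <- seq(round(lags_ms[1] / 1000 * sample_rate),
                     round(lags_ms[2] / 1000 * sample_rate))
  L <- length(lag_samples)
  span <- max(lag_samples) - min(lag_samples)
  ws <- list(N = N, L = L, C = nrow(responses[[1]]),
             lag_samples = lag_samples,
             lag_times = lag_samples / sample_rate,
             sample_rate = sample_rate,
             A = vector("list", N),    # X_i' X_i (train, full rows)
             B = vector("list", N),    # X_i' r_i (train)
             Xs = vector("list", N),   # trimmed design rows (scoring)
             As = vector("list", N),   # Xs' Xs
             cs = vector("list", N),   # colSums(Xs)
             y_trim = vector("list", N),
             n_trim = integer(N),
             eig_cache = new.env(parent = emptyenv()))
  for (i in seq_len(N)) {
    X <- lagged_matrix(envelopes[[i]], lag_samples)
    T <- nrow(X)
    stop_if_not(T > 2 * span + 2, "trial %d too short for the lag range", i)
    ws$A[[i]] <- crossprod(X)
    ws$B[[i]] <- crossprod(X, t(responses[[i]]))
    trim <- (span + 1):(T - span)
    Xs <- X[trim, , drop = FALSE]
    ws$Xs[[i]] <- Xs
    ws$As[[i]] <- crossprod(Xs)
    ws$cs[[i]] <- colSums(Xs)
    ws$y_trim[[i]] <- responses[[i]][, trim, drop = FALSE]
    ws$n_trim[i] <- length(trim)
  }
  ws$A_tot <- Reduce(`+`, ws$A)
  ws$B_tot <- Reduce(`+`, ws$B)
  ws
}

## Eigendecomposition of the summed autocovariance leaving out `drop`
## trials, cached (depends only on the envelope subset, not the pairing).
ws_eigen <- function(ws, drop = integer(0)) {
  key <- if (length(drop)) paste(sort(drop), collapse = "_") else "full"
  if (!is.null(ws$eig_cache[[key]])) return(ws$eig_cache[[key]])
  A <- ws$A_tot
  for (j in drop) A <- A - ws$A[[j]]
  e <- eigen(A, symmetric = TRUE)
  ws$eig_cache[[key]] <- e
  e
}

## Regularized solve: kernel = pinv_tol(A) %*% B with eigenvalue-mass cutoff.
solve_tol <- function(e, B, tolerance) {
  lam <- pmax(e$values, 0)
  total <- sum(lam)
  keep <- which(cumsum(lam) <= tolerance * total + 1e-12)
  if (!length(keep)) keep <- 1L
  keep <- keep[lam[keep] > 1e-12 * lam[1]]
  V <- e$vectors[, keep, drop = FALSE]
  V %*% ((crossprod(V, B)) / lam[keep])
}

## Kernel (L x C) estimated on the training set excluding `drop`.
ws_kernel <- function(ws, hp, drop = integer(0)) {
  train <- setdiff(seq_len(ws$N), drop)
  stop_if_not(length(train) >= 1, "no training trials left")
  B <- 0
  for (i in train) B <- B + ws$B[[i]]
  K <- solve_tol(ws_eigen(ws, drop), B, hp$tolerance)
  if (hp$sparseness > 0) {
    stop_if_not(length(train) >= 3,
                "sparseness thresholding needs at least 3 training trials")
    jk <- vapply(train, function(i)
      as.numeric(solve_tol(ws_eigen(ws, c(drop, i)), B - ws$B[[i]], hp$tolerance)),
      numeric(ws$L * ws$C))
    K[jackknife_unstable(jk, hp$sparseness)] <- 0
  }
  K
}

## Coefficients whose jackknife |mean|/SE falls below the threshold.
## jk: (L*C) x n_folds matrix of vectorized kernels.
jackknife_unstable <- function(jk, sparseness) {
  nj <- ncol(jk)
  mu <- rowMeans(jk)
  se <- sqrt((nj - 1) / nj * rowSums((jk - mu)^2))
  abs(mu) / pmax(se, 1e-300) < sparseness
}

## Pearson r per channel between the prediction Xs %*% K and the trimmed
## response of trial j (response index k), from precomputed moments.
ws_score <- function(ws, K, j, k = j) {
  y <- ws$y_trim[[k]]
  nt <- ws$n_trim[j]
  stop_if_not(ncol(y) == nt, "paired trials have unequal lengths")
  Sy <- rowSums(y); Syy <- rowSums(y^2)
  Sxy <- crossprod(K, crossprod(ws$Xs[[j]], t(y)))   # C x C; need diagonal
  Sxy <- diag(as.matrix(Sxy))
  Shat <- as.numeric(crossprod(K, ws$cs[[j]]))
  Shh <- colSums(K * (ws$As[[j]] %*% K))
  num <- Sxy - Shat * Sy / nt
  den <- sqrt(pmax(Shh - Shat^2 / nt, 0) * pmax(Syy - Sy^2 / nt, 0))
  r <- ifelse(den > 0, num / den, 0)
  pmin(pmax(r, -1), 1)
}

## ---- public API ------------------------------------------------------------

#' Estimate a temporal response function
#'
#' Normalized reverse correlation over a set of trials: the kernel solves
#' the pooled lag-domain normal equations, with the stimulus
#' autocovariance pseudo-inverted after the tolerance cutoff and, if
#' `hp$sparseness > 0`, coefficients zeroed where their jackknife
#' |mean|/SE stability ratio falls below the threshold.
#'
#' @param envelopes list of per-trial stimulus envelopes.
#' @param responses list of per-trial responses (channels x samples
#'   matrices, or vectors for a single channel).
#' @param sample_rate sample rate in Hz (shared by stimulus and response).
#' @param lags lag range in ms, default `c(-50, 400)`.
#' @param hp a [trf_hyperparams()] object.
#' @param compute_power if `TRUE` and there are >= 3 trials, fill
#'   `predictive_power` with leave-one-out per-channel Pearson r
#'   (edge-trimmed; see Details).
#' @details Predictive power discards one lag-range worth of samples at
#'   each trial edge before correlating, avoiding convolution edge
#'   artefacts.
#' @return object of class `trf_model`: `kernel` (channels x lags),
#'   `lag_times` (s), `hp`, `predictive_power` (per channel, or `NA`),
#'   `n_trials`.
#' @export
estimate_trf <- function(envelopes, responses, sample_rate,
                         lags = c(-50, 400), hp = trf_hyperparams(),
                         compute_power = FALSE) {
  ws <- trf_workspace(envelopes, responses, sample_rate, lags)
  K <- ws_kernel(ws, hp)
  power <- rep(NA_real_, ws$C)
  if (compute_power && ws$N >= 3) {
    r <- matrix(0, ws$N, ws$C)
    for (j in seq_len(ws$N)) {
      Kj <- ws_kernel(ws, hp, drop = j)
      r[j, ] <- ws_score(ws, Kj, j)
    }
    power <- colMeans(r)
  }
  structure(list(kernel = t(K), lag_times = ws$lag_times, hp = hp,
                 predictive_power = power, n_trials = ws$N,
                 sample_rate = sample_rate),
            class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf("TRF: %d channels x %d lags (%g..%g ms), %d trials, tol %.3g, sparse %.3g\n",
              nrow(x$kernel), ncol(x$kernel), 1000 * min(x$lag_times),
              1000 * max(x$lag_times), x$n_trials,
              x$hp$tolerance, x$hp$sparseness))
  if (!all(is.na(x$predictive_power)))
    cat(sprintf("  mean predictive power r = %.3f\n", mean(x$predictive_power)))
  invisible(x)
}

#' Predict a response from a TRF model
#'
#' @param model a `trf_model`.
#' @param envelope stimulus envelope at the model's sample rate.
#' @return channels x samples matrix of predicted responses.
#' @export
trf_predict <- function(model, envelope) {
  lag_samples <- round(model$lag_times * model$sample_rate)
  X <- lagged_matrix(envelope, lag_samples)
  t(X %*% t(model$kernel))
}

#' Select TRF hyperparameters by jackknife cross-validation
#'
#' For every grid point, estimates the TRF on N-1 trials and predicts the
#' left-out trial, for all N folds; the score is the Pearson correlation
#' between predicted and recorded response, averaged over folds and
#' channels. Returns the grid point with the highest score.
#'
#' @param envelopes,responses,sample_rate,lags as in [estimate_trf()].
#' @param grid list of [trf_hyperparams()] (or a data frame with columns
#'   `tolerance` and `sparseness`).
#' @return list with `best` (a `trf_hyperparams`), `cv_table` (data frame
#'   of grid points and scores) and `scores_by_fold`.
#' @export
jackknife_cv <- function(envelopes, responses, sample_rate,
                         lags = c(-50, 400), grid = NULL) {
  ws <- trf_workspace(envelopes, responses, sample_rate, lags)
  jackknife_cv_ws(ws, grid)
}

## CV core operating on a prebuilt workspace (reused by the pipeline).
jackknife_cv_ws <- function(ws, grid) {
  if (is.data.frame(grid))
    grid <- lapply(seq_len(nrow(grid)),
                   function(i) trf_hyperparams(grid$tolerance[i], grid$sparseness[i]))
  stop_if_not(length(grid) >= 1, "empty hyperparameter grid")
  stop_if_not(ws$N >= 3, "jackknife cross-validation needs at least 3 trials")
  scores <- matrix(0, length(grid), ws$N)
  for (g in seq_along(grid)) {
    for (j in seq_len(ws$N)) {
      Kj <- ws_kernel(ws, grid[[g]], drop = j)
      scores[g, j] <- mean(ws_score(ws, Kj, j))
    }
  }
  mean_scores <- rowMeans(scores)
  best <- which.max(mean_scores)
  cv_table <- data.frame(
    tolerance = vapply(grid, `[[`, 0, "tolerance"),
    sparseness = vapply(grid, `[[`, 0, "sparseness"),
    score = mean_scores)
  list(best = grid[[best]], cv_table = cv_table, scores_by_fold = scores)
}

#' Permutation null for TRF predictive power
#'
#' Re-pairs envelopes with non-matching responses (derangements: no trial
#' keeps its own response), re-estimates the TRF and re-scores the
#' leave-one-out predictive power for each permutation, yielding a null
#' distribution for the observed mean r.
#'
#' @param envelopes,responses,sample_rate,lags as in [estimate_trf()];
#'   all trials must have equal length.
#' @param hp a [trf_hyperparams()].
#' @param n_perm number of mismatched pairings (default 1000).
#' @param seed integer seed.
#' @return a `perm_test` with the observed mean r, null distribution and
#'   add-one p-value.
#' @export
predictive_power_null <- function(envelopes, responses, sample_rate,
                                  lags = c(-50, 400), hp = trf_hyperparams(),
                                  n_perm = 1000, seed = 1) {
  N <- length(envelopes)
  stop_if_not(N >= 3, "need at least 3 trials for mismatched pairings")
  lens <- vapply(envelopes, length, 0L)
  stop_if_not(length(unique(lens)) == 1,
              "mismatched pairing requires equal-length trials")
  ws <- trf_workspace(envelopes, responses, sample_rate, lags)
  # cross moments for arbitrary pairings
  cross <- function(i, k) {
    if (k == i) return(ws$B[[i]])
    key <- paste0("x", i, "_", k)
    if (is.null(ws$eig_cache[[key]]))
      ws$eig_cache[[key]] <- crossprod(lagged_matrix(envelopes[[i]], ws$lag_samples),
                                       t(if (is.null(dim(responses[[k]])))
                                         matrix(responses[[k]], 1) else responses[[k]]))
    ws$eig_cache[[key]]
  }
  score_pairing <- function(pair) {
    r <- numeric(ws$N)
    B_tot <- 0
    for (i in seq_len(N)) B_tot <- B_tot + cross(i, pair[i])
    for (j in seq_len(N)) {
      e <- ws_eigen(ws, j)
      K <- solve_tol(e, B_tot - cross(j, pair[j]), hp$tolerance)
      if (hp$sparseness > 0) {
        train <- setdiff(seq_len(N), j)
        jk <- vapply(train, function(i)
          as.numeric(solve_tol(ws_eigen(ws, c(j, i)),
                               B_tot - cross(j, pair[j]) - cross(i, pair[i]),
                               hp$tolerance)),
          numeric(ws$L * ws$C))
        K[jackknife_unstable(jk, hp$sparseness)] <- 0
      }
      r[j] <- mean(ws_score(ws, K, j, pair[j]))
    }
    mean(r)
  }
  observed <- score_pairing(seq_len(N))
  null <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    repeat {
      pair <- sample.int(N)
      if (!any(pair == seq_len(N))) break
    }
    score_pairing(pair)
  }, 0))
  structure(list(observed_stat = observed, null_distribution = null,
                 p = add_one_p(null, observed, "one_sided_greater"),
                 n_perm = n_perm, tail = "one_sided_greater", seed = seed,
                 scheme = "derangement"),
            class = "perm_test")
}

#' Compare per-participant TRFs between conditions
#'
#' Stacks the per-participant kernels into participants x channels x lags
#' arrays and delegates to [cluster_permutation()]; if a ROI map is given,
#' channel kernels are additionally averaged within ROI and compared with
#' [windowed_roi_trf_test()].
#'
#' @param models_a,models_b lists of `trf_model`s (same participants).
#' @param adjacency channel adjacency matrix for the scalp-level cluster
#'   test.
#' @param roi_map optional data frame with columns `channel` and `roi`.
#' @param threshold_p,n_perm,seed passed through.
#' @return list with `scalp` (a `cluster_test`) and `roi` (a
#'   `cluster_test` over ROIs x 20 ms windows, or `NULL`).
#' @export
compare_trf_conditions <- function(models_a, models_b, adjacency,
                                   roi_map = NULL, threshold_p = 0.05,
                                   n_perm = 1000, seed = 1) {
  stop_if_not(length(models_a) == length(models_b) && length(models_a) >= 4,
              "need matched per-participant model lists (n >= 4)")
  lt <- models_a[[1]]$lag_times
  for (m in c(models_a, models_b))
    stop_if_not(isTRUE(all.equal(m$lag_times, lt)), "lag axes differ across models")
  n <- length(models_a)
  C <- nrow(models_a[[1]]$kernel); L <- length(lt)
  arr <- function(models) {
    a <- array(0, c(n, C, L))
    for (i in seq_len(n)) a[i, , ] <- models[[i]]$kernel
    a
  }
  a <- arr(models_a); b <- arr(models_b)
  scalp <- cluster_permutation(a, b, adjacency, threshold_p, n_perm, seed)
  attr(scalp, "lag_times") <- lt
  roi <- NULL
  if (!is.null(roi_map)) {
    rois <- unique(roi_map$roi)
    ra <- array(0, c(n, length(rois), L)); rb <- ra
    for (k in seq_along(rois)) {
      ch <- roi_map$channel[roi_map$roi == rois[k]]
      ra[, k, ] <- apply(a[, ch, , drop = FALSE], c(1, 3), mean)
      rb[, k, ] <- apply(b[, ch, , drop = FALSE], c(1, 3), mean)
    }
    roi <- windowed_roi_trf_test(ra, rb, lt, threshold_p = threshold_p,
                                 n_perm = n_perm, seed = derive_seed(seed, 1))
    attr(roi, "rois") <- rois
  }
  list(scalp = scalp, roi = roi)
}

#' Export a TRF kernel as TSV
#'
#' Columns: `channel`, `lag_ms`, `weight`.
#'
#' @param model a `trf_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trf_tsv <- function(model, path) {
  df <- data.frame(channel = rep(seq_len(nrow(model$kernel)), ncol(model$kernel)),
                   lag_ms = rep(1000 * model$lag_times, each = nrow(model$kernel)),
                   weight = as.numeric(model$kernel))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
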