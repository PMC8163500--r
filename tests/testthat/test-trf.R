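# TRF estimation by normalized reverse correlation, jackknife CV and the
# mismatched-pairing null.

sr_trf <- 200

# biphasic reference kernel with peaks at +80 ms and -140 ms
true_kernel_fix <- local({
  lagt <- seq(0, 0.3, by = 1 / sr_trf)
  k <- exp(-0.5 * ((lagt - 0.08) / 0.012)^2) -
    0.8 * exp(-0.5 * ((lagt - 0.14) / 0.018)^2)
  attr(k, "lag_times") <- lagt
  k
})

# place the reference kernel on the estimation lag grid (-50..400 ms)
pad_true_kernel <- function(lag_times) {
  out <- numeric(length(lag_times))
  src <- attr(true_kernel_fix, "lag_times")
  out[match(round(src * sr_trf), round(lag_times * sr_trf))] <- true_kernel_fix
  out
}

make_trf_data <- function(n_trials, dur_s, snr_db, seed, cutoff = 30) {
  withr::with_seed(seed, {
    envs <- lapply(seq_len(n_trials), function(i)
      hftag:::attended_envelope_sim(dur_s * sr_trf, sr_trf, cutoff))
    rsps <- lapply(envs, function(e) {
      sig <- hftag:::conv_causal(e - mean(e), as.numeric(true_kernel_fix))
      matrix(sig + pink_noise(length(e), 1) * stats::sd(sig) / 10^(snr_db / 20), 1)
    })
    list(envs = envs, rsps = rsps)
  })
}

test_that("a pure delay system yields a unit impulse at the delay lag", {
  withr::with_seed(1, {
    envs <- lapply(1:4, function(i) stats::rnorm(2000))
    rsps <- lapply(envs, function(e) matrix(c(rep(0, 20), e[1:1980]), 1)) # 100 ms
  })
  m <- estimate_trf(envs, rsps, sr_trf, c(-50, 400), trf_hyperparams(1, 0))
  pk <- which.max(abs(m$kernel[1, ]))
  expect_equal(1000 * m$lag_times[pk], 100)
  # side-lobe energy below 5%
  expect_lt(1 - max(m$kernel^2) / sum(m$kernel^2), 0.05)
  # white stimulus, tolerance 1: equals the direct normal-equation solve
  X <- do.call(rbind, lapply(envs, hftag:::lagged_matrix,
                             lag_samples = seq(-10, 80)))
  y <- unlist(lapply(rsps, as.numeric))
  k_direct <- solve(crossprod(X), crossprod(X, y))
  expect_equal(m$kernel[1, ], as.numeric(k_direct), tolerance = 1e-8)
})

test_that("estimator is linear in the response and rejects degenerate input", {
  d <- make_trf_data(3, 8, 10, seed = 2)
  m1 <- estimate_trf(d$envs, d$rsps, sr_trf, c(-50, 400), trf_hyperparams(1, 0))
  m3 <- estimate_trf(d$envs, lapply(d$rsps, function(r) 3 * r), sr_trf,
                     c(-50, 400), trf_hyperparams(1, 0))
  expect_equal(m3$kernel, 3 * m1$kernel, tolerance = 1e-12)
  expect_error(estimate_trf(list(rep(1, 2000)), list(matrix(0, 1, 2000)),
                            sr_trf, c(-50, 400)),
               "constant")
})

test_that("biphasic kernel is recovered through 0 dB 1/f noise from 20 trials", {
  d <- make_trf_data(20, 30, 0, seed = 3)
  m <- estimate_trf(d$envs, d$rsps, sr_trf, c(-50, 400),
                    trf_hyperparams(0.999, 0))
  truth <- pad_true_kernel(m$lag_times)
  expect_gt(stats::cor(m$kernel[1, ], truth), 0.9)
  # injected peak lags (80 and 140 ms) recovered within one 5 ms bin
  expect_lte(abs(1000 * m$lag_times[which.max(m$kernel[1, ])] - 80), 5)
  expect_lte(abs(1000 * m$lag_times[which.min(m$kernel[1, ])] - 140), 5)
})

test_that("sparseness thresholding suppresses unstable coefficients only", {
  d <- make_trf_data(6, 10, 0, seed = 4)
  m0 <- estimate_trf(d$envs, d$rsps, sr_trf, c(-50, 400),
                     trf_hyperparams(0.999, 0))
  m2 <- estimate_trf(d$envs, d$rsps, sr_trf, c(-50, 400),
                     trf_hyperparams(0.999, 2))
  truth <- pad_true_kernel(m2$lag_times)
  support <- abs(truth) > 0.3
  # thresholding zeroes some coefficients, but not the kernel's core
  expect_gt(sum(m2$kernel == 0), 0)
  expect_true(all(m2$kernel[1, support] != 0))
  expect_gte(stats::cor(m2$kernel[1, ], truth), stats::cor(m0$kernel[1, ], truth) - 0.02)
})

test_that("jackknife CV selects sensible regularization", {
  grid <- data.frame(tolerance = c(1, 0.999, 0.95), sparseness = 0)
  # single grid point: returned as-is
  d <- make_trf_data(4, 8, 10, seed = 5)
  cv1 <- jackknife_cv(d$envs, d$rsps, sr_trf, c(-50, 400),
                      grid = data.frame(tolerance = 0.97, sparseness = 0.5))
  expect_equal(cv1$best$tolerance, 0.97)
  expect_equal(cv1$best$sparseness, 0.5)
  expect_error(jackknife_cv(d$envs, d$rsps, sr_trf, c(-50, 400), grid = list()),
               "empty")
  # noiseless, well-conditioned data: no regularization wanted
  d0 <- make_trf_data(4, 10, 120, seed = 6)
  cv0 <- jackknife_cv(d0$envs, d0$rsps, sr_trf, c(-50, 400), grid = grid)
  expect_equal(cv0$best$tolerance, 1)
  # noisy short trials with a smooth stimulus: the middle tolerance beats
  # both grid extremes more often than not (sign test over 20 seeds)
  wins_full <- 0; wins_low <- 0; n_informative <- 0
  for (s in 1:20) {
    dn <- make_trf_data(4, 8, -10, seed = 100 + s, cutoff = 20)
    cvn <- jackknife_cv(dn$envs, dn$rsps, sr_trf, c(-50, 400), grid = grid)
    sc <- cvn$cv_table$score
    wins_full <- wins_full + (sc[2] > sc[1])
    wins_low <- wins_low + (sc[2] > sc[3])
    n_informative <- n_informative + 1
  }
  expect_lt(stats::binom.test(wins_full, n_informative, alternative = "greater")$p.value, 0.05)
  expect_lt(stats::binom.test(wins_low, n_informative, alternative = "greater")$p.value, 0.05)
  # deterministic: identical inputs give bit-identical scores
  cv_a <- jackknife_cv(d$envs, d$rsps, sr_trf, c(-50, 400), grid = grid)
  cv_b <- jackknife_cv(d$envs, d$rsps, sr_trf, c(-50, 400), grid = grid)
  expect_identical(cv_a$cv_table, cv_b$cv_table)
})

test_that("predictive power clears the mismatched-pairing null only for matched data", {
  d <- make_trf_data(10, 10, 0, seed = 7)
  pn <- predictive_power_null(d$envs, d$rsps, sr_trf, c(-50, 400),
                              trf_hyperparams(0.999, 0), n_perm = 99, seed = 1)
  expect_lte(pn$p, 0.01)
  expect_gt(pn$observed_stat, 0.2)
  # minimum attainable p with 19 permutations is 0.05
  pn19 <- predictive_power_null(d$envs, d$rsps, sr_trf, c(-50, 400),
                                trf_hyperparams(0.999, 0), n_perm = 19, seed = 2)
  expect_equal(pn19$p, 0.05)
  # responses replaced by fresh noise: observed power sits inside the null
  dn <- withr::with_seed(8, lapply(1:10, function(i) matrix(pink_noise(2000, 1), 1)))
  pn0 <- predictive_power_null(d$envs, dn, sr_trf, c(-50, 400),
                               trf_hyperparams(0.999, 0), n_perm = 99, seed = 3)
  expect_gt(pn0$p, 0.05)
  expect_error(predictive_power_null(d$envs[1:2], d$rsps[1:2], sr_trf),
               "at least 3")
})

test_that("null p-values are uniform when no stimulus-response link exists", {
  # 200 replicates of a 6-trial no-signal experiment (6 trials give 265
  # distinct derangements, enough support for a 99-permutation null);
  # add-one p should be uniform
  ps <- vapply(1:200, function(r) {
    withr::with_seed(3000 + r, {
      envs <- lapply(1:6, function(i) hftag:::attended_envelope_sim(600, sr_trf, 20))
      rsps <- lapply(1:6, function(i) matrix(stats::rnorm(600), 1))
    })
    predictive_power_null(envs, rsps, sr_trf, c(-50, 150),
                          trf_hyperparams(0.999, 0), n_perm = 99,
                          seed = r)$p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("condition comparison localizes kernel differences in space and lag", {
  n <- 12; C <- 6
  lag_times <- seq(-0.05, 0.4, by = 1 / sr_trf)
  L <- length(lag_times)
  mk_models <- function(effect, seed) {
    withr::with_seed(seed, lapply(seq_len(n), function(p) {
      kern <- matrix(stats::rnorm(C * L, sd = 0.3), C, L)
      win <- lag_times >= 0.07 & lag_times <= 0.18
      kern[1:2, win] <- kern[1:2, win] + effect
      structure(list(kernel = kern, lag_times = lag_times,
                     hp = trf_hyperparams(), predictive_power = rep(NA_real_, C),
                     n_trials = 5, sample_rate = sr_trf), class = "trf_model")
    }))
  }
  base <- mk_models(0, 11)
  adj <- grid_adjacency(3, 2)
  cmp0 <- compare_trf_conditions(base, base, adj, n_perm = 100, seed = 1)
  expect_length(cmp0$scalp$clusters, 0)
  # enhancement at 70-180 ms on channels 1-2 is found there and only there
  enh <- mk_models(0.6, 11)
  roi_map <- data.frame(channel = 1:6, roi = rep(c("L_A", "L_B", "R_A"), each = 2))
  cmp <- compare_trf_conditions(enh, base, adj, roi_map = roi_map,
                                n_perm = 300, seed = 2)
  expect_gte(length(cmp$scalp$clusters), 1)
  top <- cmp$scalp$clusters[[1]]
  expect_lt(top$corrected_p, 0.05)
  expect_true(all(top$members[, "unit"] %in% c(1, 2)))
  t_range <- range(lag_times[top$members[, "bin"]])
  expect_gte(t_range[1], 0.05)
  expect_lte(t_range[2], 0.20)
  # ROI variant flags exactly the ROI carrying the effect
  expect_gte(length(cmp$roi$clusters), 1)
  rois <- attr(cmp$roi, "rois")
  expect_equal(unique(rois[cmp$roi$clusters[[1]]$members[, "unit"]]), "L_A")
  # mismatched lag axes are refused
  bad <- base
  bad[[1]]$lag_times <- bad[[1]]$lag_times + 0.005
  expect_error(compare_trf_conditions(bad, base, adj), "lag axes")
})
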