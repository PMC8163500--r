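## Synthetic syllable tokens ------------------------------------------------
##
## Real recorded syllables are replaced by synthetic tokens that keep the
## only properties the downstream analysis relies on: every token lasts
## exactly 250 ms, tokens are acoustically distinct, intensity (RMS) is
## equated across the bank, and a truncated token fades out over its last
## 25 ms. Each token is band-limited noise shaped by a token-specific
## amplitude contour. The bank is split into two phonotactic classes --
## "onset" tokens with an abrupt, early-peaked contour (plosive-like) and
## "coda" tokens with a gradual, late-peaked contour (sonorant-like).
## Structured sentences place onset-class tokens word-initially and
## coda-class tokens word-finally, which is what makes a word-rate (2 Hz)
## component appear in the modulation spectrum of Structured sequences
## without any explicit 2 Hz modulation being injected.

SYLLABLE_DUR <- 0.25 # seconds, fixed by the paradigm
FADE_DUR <- 0.025    # seconds, fade-out applied to the kernel tail
TOKEN_RMS <- 0.1     # common RMS intensity of every rendered token

#' Create a bank of synthetic syllable tokens
#'
#' Generates `n_tokens` distinct, intensity-equated syllable tokens of
#' exactly 250 ms each. Tokens are band-limited noise bursts under a
#' token-specific smooth amplitude contour; the last 25 ms of every
#' amplitude kernel decays monotonically to zero. Half of the bank is
#' assigned to the word-initial ("onset") contour class and half to the
#' word-final ("coda") class.
#'
#' @param n_tokens number of tokens (at least 8, one full sentence).
#' @param sample_rate audio sample rate in Hz (at least 200).
#' @param seed integer seed; all randomness in the bank flows from it.
#' @return an object of class `syllable_bank`: a list of `syllable_token`
#'   objects plus the sample rate. Each token carries `token_id`, `class`,
#'   `envelope_kernel` (amplitude contour, one value per sample),
#'   `waveform` (rendered audio) and `carrier_spec` (centre frequency and
#'   bandwidth of the noise carrier).
#' @export
make_syllable_bank <- function(n_tokens, sample_rate = 1000, seed = 1) {
  stop_if_not(is_count(n_tokens, min = 8),
              "`n_tokens` must be an integer >= 8 (one full 8-syllable sentence)")
  stop_if_not(is_scalar_num(sample_rate) && sample_rate >= 200,
              "`sample_rate` must be >= 200 Hz")
  n <- round(SYLLABLE_DUR * sample_rate)
  n_onset <- ceiling(n_tokens / 2)
  classes <- rep(c("onset", "coda"), c(n_onset, n_tokens - n_onset))
  tokens <- with_seed(seed, lapply(seq_len(n_tokens), function(i) {
    synth_token(i, classes[i], n, sample_rate)
  }))
  structure(list(tokens = tokens, sample_rate = sample_rate,
                 n_samples = n, seed = seed),
            class = "syllable_bank")
}

## One token: contour class base shape x smooth multiplicative perturbation,
## noise carrier, exact-RMS normalization, monotone 25 ms tail fade.
synth_token <- function(token_id, class, n, sample_rate) {
  t <- (seq_len(n) - 0.5) / sample_rate
  if (class == "onset") {
    peak <- 0.050; shape <- 2.4
  } else {
    peak <- 0.070; shape <- 3.0
  }
  # token-specific jitter of the contour peak time (acoustic diversity)
  peak <- peak * exp(stats::runif(1, -0.15, 0.15))
  base <- (t / peak)^shape * exp(shape * (1 - t / peak))
  # vocalic energy dies out before the 250 ms slot ends (the real tokens
  # averaged ~244 ms and were silence-padded), deepening the 4 Hz modulation
  gate <- rep(1, n)
  g0 <- t >= 0.170 & t < 0.220
  gate[g0] <- cos(pi / 2 * (t[g0] - 0.170) / 0.050)^2
  gate[t >= 0.220] <- 0
  base <- base * gate
  # token-specific smooth perturbation (lognormal, ~25 ms correlation)
  z <- stats::rnorm(n)
  w <- max(2L, round(0.025 * sample_rate))
  z <- moving_average_reflect(z, w)
  z <- z / max(stats::sd(z), 1e-12)
  env <- base * exp(0.30 * z)
  # monotone linear fade to zero over the final 25 ms
  nf <- max(2L, round(FADE_DUR * sample_rate))
  fade_idx <- (n - nf + 1L):n
  v0 <- env[n - nf + 1L]
  env[fade_idx] <- v0 * rev(seq_len(nf) - 1L) / (nf - 1L)

  cf <- exp(stats::runif(1, log(0.10), log(0.40))) * sample_rate / 2
  bw <- cf / 3
  carrier <- bandpass_noise(n, sample_rate, cf, bw)
  wav <- carrier * env
  s <- TOKEN_RMS / sqrt(mean(wav^2))
  structure(list(token_id = token_id, class = class,
                 envelope_kernel = env * s, waveform = wav * s,
                 carrier_spec = list(center_freq = cf, bandwidth = bw),
                 sample_rate = sample_rate),
            class = "syllable_token")
}

## Unit-RMS Gaussian-band noise via FFT-domain shaping.
bandpass_noise <- function(n, sample_rate, center, bandwidth) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, sample_rate, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, sample_rate - f) # two-sided frequency axis
  mask <- exp(-0.5 * ((f - center) / bandwidth)^2)
  y <- Re(stats::fft(X * mask, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

#' @export
print.syllable_bank <- function(x, ...) {
  cls <- table(vapply(x$tokens, `[[`, "", "class"))
  cat(sprintf("syllable bank: %d tokens (%s), %d samples each @ %g Hz\n",
              length(x$tokens),
              paste(sprintf("%d %s", cls, names(cls)), collapse = ", "),
              x$n_samples, x$sample_rate))
  invisible(x)
}

token_ids_of_class <- function(bank, class) {
  ids <- vapply(bank$tokens, `[[`, 0L, "token_id")
  ids[vapply(bank$tokens, `[[`, "", "class") == class]
}
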