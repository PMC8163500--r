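## Synthetic neural recordings ----------------------------------------------
##
## The simulator produces multi-channel recordings with exactly the
## statistical structure the analysis pipeline assumes, plus a ground-truth
## record for recovery tests:
##   * an evoked response to every syllable onset (4 Hz train convolved
##     with a biphasic kernel) on all channels -- the obligatory auditory
##     response present in both conditions;
##   * in the Structured condition only, a 1 Hz sinusoid phase-locked to
##     sentence onsets, confined to a designated channel group -- the
##     phrase-level tracking response (phase fixed within a participant,
##     random across participants);
##   * a linear speech-tracking response: a true temporal response function
##     convolved with the attended-speech envelope, with a condition
##     difference confined to a 70-180 ms window on selected channels;
##   * 1/f background noise, independent across channels.
## Anatomical source estimation is out of scope; channels carry ROI labels
## (an abstract channel-group -> region map) so ROI-level statistics can be
## exercised on labeled groups.

#' Simulation configuration
#'
#' Defaults describe the experiment at its published scale: 29 participants,
#' 15 trials per condition, 22 sentences (44 s) per trial, 250 Hz neural
#' sampling. Response amplitudes are calibrated (see the package vignette)
#' so that the syllable-rate ITPC peak has a large effect size (Cohen's
#' d > 1.5) and the phrase-rate peak a moderate one (d ~ 0.6), matching the
#' effect-size regime the analysis is meant to operate in.
#'
#' @param n_participants number of participants (default 29).
#' @param n_channels number of channels (default 16; must be a multiple of 8
#'   so the default ROI map can label them).
#' @param n_trials_per_condition trials per condition (default 15).
#' @param sample_rate neural sample rate in Hz (default 200, which puts the
#'   250 ms syllable grid exactly on samples).
#' @param n_sentences_per_trial trial length in 2 s sentences (default 22).
#' @param syllable_response_amp amplitude of the evoked syllable response.
#' @param phrase_response_amp amplitude of the 1 Hz phrase-tracking
#'   sinusoid (Structured condition, `phrase_channels` only).
#' @param phrase_channels channel indices carrying the phrase response.
#' @param trf_amp amplitude of the speech-tracking (TRF) response.
#' @param trf_effect_amp amplitude of the Structured-condition TRF
#'   enhancement in the 70-180 ms window.
#' @param trf_effect_channels channels carrying the TRF condition effect.
#' @param trf_effect_window lag window (s) of the TRF condition effect.
#' @param noise_exponent spectral exponent of the 1/f background noise.
#' @param noise_amp noise standard deviation.
#' @param participant_gain_sd log-normal SD of per-participant response gain.
#' @param seed master seed for the whole simulated experiment.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 29,
                       n_channels = 16,
                       n_trials_per_condition = 15,
                       sample_rate = 200,
                       n_sentences_per_trial = 22,
                       syllable_response_amp = 0.5,
                       phrase_response_amp = 0.022,
                       phrase_channels = 3:6,
                       trf_amp = 0.15,
                       trf_effect_amp = 0.05,
                       trf_effect_channels = 3:4,
                       trf_effect_window = c(0.070, 0.180),
                       noise_exponent = 1,
                       noise_amp = 1,
                       participant_gain_sd = 0.2,
                       seed = 1) {
  stop_if_not(is_count(n_participants), "`n_participants` must be a positive integer")
  stop_if_not(is_count(n_channels, 2), "`n_channels` must be >= 2")
  stop_if_not(is_count(n_trials_per_condition), "`n_trials_per_condition` must be >= 1")
  stop_if_not(is_scalar_num(sample_rate) && sample_rate >= 20,
              "`sample_rate` must be >= 20 Hz")
  stop_if_not(is_count(n_sentences_per_trial, 2),
              "`n_sentences_per_trial` must be >= 2")
  for (a in c(syllable_response_amp, phrase_response_amp, trf_amp,
              trf_effect_amp, noise_amp))
    stop_if_not(is_scalar_num(a) && a >= 0, "amplitudes must be >= 0")
  stop_if_not(is_scalar_num(noise_exponent) && noise_exponent >= 0,
              "`noise_exponent` must be >= 0")
  stop_if_not(all(phrase_channels %in% seq_len(n_channels)),
              "`phrase_channels` must be a subset of channels")
  stop_if_not(all(trf_effect_channels %in% seq_len(n_channels)),
              "`trf_effect_channels` must be a subset of channels")
  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    n_channels = as.integer(n_channels),
    n_trials_per_condition = as.integer(n_trials_per_condition),
    sample_rate = sample_rate,
    n_sentences_per_trial = as.integer(n_sentences_per_trial),
    syllable_response_amp = syllable_response_amp,
    phrase_response_amp = phrase_response_amp,
    phrase_channels = as.integer(phrase_channels),
    trf_amp = trf_amp,
    trf_effect_amp = trf_effect_amp,
    trf_effect_channels = as.integer(trf_effect_channels),
    trf_effect_window = trf_effect_window,
    noise_exponent = noise_exponent,
    noise_amp = noise_amp,
    participant_gain_sd = participant_gain_sd,
    seed = as.integer(seed)), class = "sim_config")
  cfg$roi_map <- default_roi_map(cfg$n_channels)
  cfg$trf_kernel_true <- true_trf_kernels(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d participants x 2 x %d trials, %d channels",
                     " @ %g Hz, %d sentences/trial (seed %d)\n"),
              x$n_participants, x$n_trials_per_condition, x$n_channels,
              x$sample_rate, x$n_sentences_per_trial, x$seed))
  invisible(x)
}

#' Default channel -> ROI label map
#'
#' Channels are split into left/right hemisphere halves, each subdivided
#' into auditory, inferior-frontal, posterior-parietal and occipital
#' groups. This is an abstract stand-in for an anatomical parcellation.
#'
#' @param n_channels number of channels (multiple of 8).
#' @return data frame with columns `channel`, `hemisphere`, `roi`.
#' @export
default_roi_map <- function(n_channels) {
  stop_if_not(n_channels %% 8 == 0, "default ROI map needs a multiple of 8 channels")
  per <- n_channels %/% 8
  rois <- c("AUD", "IFG", "PPC", "OCC")
  data.frame(
    channel = seq_len(n_channels),
    hemisphere = rep(c("L", "R"), each = n_channels / 2),
    roi = paste(rep(rep(c("L", "R"), each = n_channels / 2), 1),
                rep(rep(rois, each = per), 2), sep = "_"))
}

## Biphasic evoked-response kernel, 150 ms support: positive deflection
## near 50 ms followed by a negative one near 120 ms.
evoked_response_kernel <- function(sample_rate) {
  t <- seq(0, 0.150, by = 1 / sample_rate)
  k <- exp(-0.5 * ((t - 0.050) / 0.015)^2) - 0.6 * exp(-0.5 * ((t - 0.115) / 0.022)^2)
  k / max(abs(k))
}

## True speech-tracking kernels: Gaussian peaks at +80 ms and -140 ms,
## strongest on auditory channels, present at half gain elsewhere. The
## kernel shape is normalized so its response to a typical attended
## envelope has unit standard deviation; `trf_amp` is then the
## speech-tracking SNR relative to the unit-SD background noise.
true_trf_kernels <- function(cfg) {
  t <- seq(0, 0.300, by = 1 / cfg$sample_rate)
  shape <- exp(-0.5 * ((t - 0.080) / 0.012)^2) - 0.8 * exp(-0.5 * ((t - 0.140) / 0.018)^2)
  ref_env <- with_seed(424243L, attended_envelope_sim(60 * cfg$sample_rate,
                                                      cfg$sample_rate))
  shape <- shape / stats::sd(conv_causal(ref_env - mean(ref_env), shape))
  gain <- rep(0.5, cfg$n_channels)
  gain[cfg$roi_map$roi %in% c("L_AUD", "R_AUD")] <- 1
  kern <- outer(gain, shape) * cfg$trf_amp
  attr(kern, "lag_times") <- t
  kern
}

## Structured-condition TRF enhancement: a smooth bump spanning the effect
## window on the effect channels, normalized (like the base kernel) so its
## response to a typical envelope has unit SD; `trf_effect_amp` is then the
## SNR of the condition difference.
trf_effect_kernel <- function(cfg) {
  t <- attr(cfg$trf_kernel_true, "lag_times")
  w <- cfg$trf_effect_window
  mid <- mean(w); hw <- diff(w) / 2
  bump <- ifelse(abs(t - mid) <= hw, cos(pi / 2 * (t - mid) / hw)^2, 0)
  ref_env <- with_seed(424243L, attended_envelope_sim(60 * cfg$sample_rate,
                                                      cfg$sample_rate))
  bump <- bump / stats::sd(conv_causal(ref_env - mean(ref_env), bump))
  eff <- matrix(0, cfg$n_channels, length(t))
  eff[cfg$trf_effect_channels, ] <- rep(bump * cfg$trf_effect_amp,
                                        each = length(cfg$trf_effect_channels))
  eff
}

#' Generate 1/f ("pink") noise
#'
#' FFT-domain synthesis: spectral amplitude proportional to
#' `f^(-exponent/2)` (power `f^-exponent`) with random phases, normalized
#' to unit variance.
#'
#' @param n number of samples.
#' @param exponent spectral exponent (0 = white).
#' @return numeric vector of length `n` with mean ~0 and SD 1.
#' @export
pink_noise <- function(n, exponent = 1) {
  stop_if_not(is_count(n, 8), "`n` must be >= 8")
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- seq_len(n) - 1L                  # 0 .. n-1
  f <- pmin(k, n - k)                   # two-sided frequency bin index
  shape <- c(0, as.numeric(f[-1])^(-exponent / 2)) # zero out DC
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  (y - mean(y)) / stats::sd(y)
}

## Smooth positive envelope standing in for an attended natural narrative:
## low-pass (< 8 Hz) Gaussian noise, shifted positive.
attended_envelope_sim <- function(n, sample_rate, cutoff = 8) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * sample_rate
  f <- pmin(f, sample_rate - f)
  X[f > cutoff] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y <- (y - mean(y)) / stats::sd(y)
  y - min(y) + 0.05
}

## Per-participant latent parameters, deterministic in (cfg$seed, id).
participant_params <- function(cfg, participant_id) {
  with_seed(derive_seed(cfg$seed, participant_id), list(
    gain = exp(stats::rnorm(1, 0, cfg$participant_gain_sd)),
    phrase_phase = stats::runif(1, 0, 2 * pi)))
}

#' Simulate one trial of neural data
#'
#' @param cfg a `sim_config`.
#' @param condition `"Structured"` or `"NonStructured"`.
#' @param task_irrelevant either a `stimulus_sequence` or an integer number
#'   of 250 ms syllables (the neural response depends only on the onset
#'   grid and the condition, so a rendered waveform is not required).
#' @param attended_envelope optional attended-speech envelope at the neural
#'   sample rate, same duration as the trial; simulated if `NULL`.
#' @param participant_id,trial_id identifiers; together with `cfg$seed`
#'   they determine the noise realization.
#' @return object of class `trial_recording` with fields `data`
#'   (channels x samples), `condition`, `attended_envelope`,
#'   `tag_onset_index` (sample of the first syllable onset, always 1),
#'   `participant_id`, `trial_id`, `sample_rate`.
#' @export
simulate_trial <- function(cfg, condition, task_irrelevant,
                           attended_envelope = NULL,
                           participant_id = 1L, trial_id = 1L) {
  stop_if_not(inherits(cfg, "sim_config"), "`cfg` must be a sim_config")
  condition <- match.arg(condition, c("Structured", "NonStructured"))
  n_syll <- if (inherits(task_irrelevant, "stimulus_sequence")) {
    length(task_irrelevant$token_ids)
  } else {
    stop_if_not(is_count(task_irrelevant), "`task_irrelevant` must be a stimulus_sequence or a syllable count")
    as.integer(task_irrelevant)
  }
  sr <- cfg$sample_rate
  n <- round(n_syll * 0.25 * sr)
  if (!is.null(attended_envelope)) {
    stop_if_not(length(attended_envelope) == n,
                "attended envelope (%d samples) does not match trial duration (%d samples)",
                length(attended_envelope), n)
  }
  pp <- participant_params(cfg, participant_id)
  seed <- derive_seed(cfg$seed, participant_id * 100000 +
                        trial_id * 10 + (condition == "Structured"))
  with_seed(seed, {
    if (is.null(attended_envelope))
      attended_envelope <- attended_envelope_sim(n, sr)
    data <- matrix(0, cfg$n_channels, n)
    # evoked syllable response, all channels
    if (cfg$syllable_response_amp > 0) {
      train <- numeric(n)
      train[round((seq_len(n_syll) - 1) * 0.25 * sr) + 1L] <- 1
      ev <- conv_causal(train, evoked_response_kernel(sr))
      data <- data + cfg$syllable_response_amp * pp$gain *
        matrix(ev, cfg$n_channels, n, byrow = TRUE)
    }
    # phrase-rate component: Structured only, phrase channels only,
    # phase-locked to sentence onsets within a participant
    if (condition == "Structured" && cfg$phrase_response_amp > 0) {
      t <- (seq_len(n) - 1) / sr
      s <- cfg$phrase_response_amp * pp$gain * sin(2 * pi * 1 * t + pp$phrase_phase)
      data[cfg$phrase_channels, ] <- data[cfg$phrase_channels, , drop = FALSE] +
        matrix(s, length(cfg$phrase_channels), n, byrow = TRUE)
    }
    # speech-tracking response to the attended envelope
    if (cfg$trf_amp > 0 || cfg$trf_effect_amp > 0) {
      kern <- cfg$trf_kernel_true
      if (condition == "Structured") kern <- kern + trf_effect_kernel(cfg)
      env0 <- attended_envelope - mean(attended_envelope)
      for (c in seq_len(cfg$n_channels)) {
        if (any(kern[c, ] != 0))
          data[c, ] <- data[c, ] + pp$gain * conv_causal(env0, kern[c, ])
      }
    }
    # 1/f background noise
    if (cfg$noise_amp > 0) {
      for (c in seq_len(cfg$n_channels))
        data[c, ] <- data[c, ] + cfg$noise_amp * pink_noise(n, cfg$noise_exponent)
    }
    structure(list(data = data, condition = condition,
                   attended_envelope = attended_envelope,
                   tag_onset_index = 1L,
                   participant_id = participant_id, trial_id = trial_id,
                   sample_rate = sr),
              class = "trial_recording")
  })
}

## Causal FIR convolution: y[t] = sum_l k[l+1] x[t-l], output length =
## length(x). FFT-based, padded to a 2-3-5-smooth length for speed.
conv_causal <- function(x, k) {
  n <- length(x)
  m <- stats::nextn(n + length(k) - 1L, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(m - n)))
  K <- stats::fft(c(k, numeric(m - length(k))))
  Re(stats::fft(X * K, inverse = TRUE))[seq_len(n)] / m
}

#' Simulate all trials of one participant
#'
#' @param cfg a `sim_config`.
#' @param participant_id participant index.
#' @return list of `trial_recording`s (both conditions interleaved).
#' @export
simulate_participant <- function(cfg, participant_id) {
  n_syll <- cfg$n_sentences_per_trial * 8L
  trials <- list()
  for (j in seq_len(cfg$n_trials_per_condition)) {
    for (cond in c("Structured", "NonStructured")) {
      trials[[length(trials) + 1L]] <-
        simulate_trial(cfg, cond, n_syll, NULL, participant_id, j)
    }
  }
  trials
}

#' Simulate a full experiment
#'
#' Materializes every trial of every participant. For large configurations
#' prefer streaming one participant at a time with [simulate_participant()]
#' (as [run_experiment()] does).
#'
#' @param cfg a `sim_config`.
#' @return list with `participants` (list of trial lists), `ground_truth`
#'   and `cfg`.
#' @export
simulate_experiment <- function(cfg) {
  stop_if_not(inherits(cfg, "sim_config"), "`cfg` must be a sim_config")
  participants <- lapply(seq_len(cfg$n_participants),
                         function(p) simulate_participant(cfg, p))
  list(participants = participants, ground_truth = ground_truth(cfg), cfg = cfg)
}

#' Ground truth of a simulated experiment
#'
#' Per-channel injected amplitudes at each tag rate, the true TRF kernels
#' and the master seed; serialized alongside every simulated dataset so
#' recovery tests can compare against it.
#'
#' @param cfg a `sim_config`.
#' @return list with `tag_amplitudes` (channels x rates data frame),
#'   `trf_kernel_true`, `trf_effect_kernel`, `seed`.
#' @export
ground_truth <- function(cfg) {
  amp <- data.frame(channel = seq_len(cfg$n_channels),
                    syllable_4hz = cfg$syllable_response_amp,
                    word_2hz = 0,
                    phrase_1hz = ifelse(seq_len(cfg$n_channels) %in% cfg$phrase_channels,
                                        cfg$phrase_response_amp, 0),
                    sentence_0.5hz = 0)
  list(tag_amplitudes = amp,
       trf_kernel_true = cfg$trf_kernel_true,
       trf_effect_kernel = trf_effect_kernel(cfg),
       noise_exponent = cfg$noise_exponent,
       seed = cfg$seed)
}

#' Simulate comprehension-question behavior
#'
#' Each participant answers 4 three-alternative multiple-choice questions
#' per trial. Answers are Bernoulli at a participant-specific accuracy rate
#' drawn from `N(mean, sd^2)` and clipped to `[1/3, 1]` (guessing floor).
#'
#' @param cfg a `sim_config` (supplies participant/trial counts).
#' @param accuracy_mean group mean accuracy (default 0.715).
#' @param accuracy_sd between-participant SD (default 0.15).
#' @param seed integer seed.
#' @return an answer table: data frame with columns `participant_id`,
#'   `trial_id`, `condition`, `question` (1-4), `correct` (logical).
#' @export
simulate_behavior <- function(cfg, accuracy_mean = 0.715, accuracy_sd = 0.15,
                              seed = 1) {
  stop_if_not(is_scalar_num(accuracy_mean) && accuracy_mean >= 0 && accuracy_mean <= 1,
              "`accuracy_mean` must be in [0, 1]")
  with_seed(seed, {
    rows <- expand.grid(question = 1:4,
                        condition = c("Structured", "NonStructured"),
                        trial_id = seq_len(cfg$n_trials_per_condition),
                        participant_id = seq_len(cfg$n_participants),
                        stringsAsFactors = FALSE)
    rate <- pmin(pmax(stats::rnorm(cfg$n_participants, accuracy_mean, accuracy_sd),
                      1 / 3), 1)
    rows$correct <- stats::runif(nrow(rows)) < rate[rows$participant_id]
    rows[, c("participant_id", "trial_id", "condition", "question", "correct")]
  })
}
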