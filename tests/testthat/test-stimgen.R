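# Stimulus construction: syllable bank, sequences, envelopes, modulation
# spectra.

test_that("syllable tokens are 250 ms, intensity-equated and distinct", {
  bank <- make_syllable_bank(32, 1000, seed = 5)
  expect_length(bank$tokens, 32)
  for (tk in bank$tokens) {
    expect_length(tk$waveform, 250)
    expect_length(tk$envelope_kernel, 250)
  }
  # RMS equated within 1e-6 relative
  rms <- vapply(bank$tokens, function(tk) sqrt(mean(tk$waveform^2)), 0)
  expect_lt(max(abs(rms - rms[1])), 1e-6 * rms[1])
  # pairwise envelope correlation < 0.99 (acoustically distinguishable)
  E <- vapply(bank$tokens, `[[`, numeric(250), "envelope_kernel")
  cc <- stats::cor(E); diag(cc) <- 0
  expect_lt(max(cc), 0.99)
  # the final 25 ms of every kernel fades monotonically to zero
  for (tk in bank$tokens) {
    tail25 <- tk$envelope_kernel[226:250]
    expect_true(all(diff(tail25) <= 1e-12))
    expect_equal(tail25[25], 0)
  }
  # a bank of 8 suffices for one sentence; smaller banks are refused
  expect_length(make_syllable_bank(8, 1000, seed = 1)$tokens, 8)
  expect_error(make_syllable_bank(7, 1000, seed = 1), ">= 8")
  expect_error(make_syllable_bank(16, 100, seed = 1), ">= 200")
  # duration contract holds at other sample rates
  expect_length(make_syllable_bank(8, 2000, seed = 1)$tokens[[1]]$waveform, 500)
})

test_that("structured sequences are whole sentences from the inventory", {
  inv <- fix_inventory()
  s1 <- build_structured_sequence(inv, 1, seed = 1)
  expect_length(s1$token_ids, 8)
  expect_equal(sequence_duration(s1), 2.0)
  s4 <- build_structured_sequence(inv, 4, seed = 1)
  expect_equal(sequence_duration(s4), 8.0)
  s22 <- build_structured_sequence(inv, 22, seed = 1)
  expect_equal(sequence_duration(s22), 44.0)
  # waveform duration matches the token count to within one sample
  expect_equal(length(s22$waveform), length(s22$token_ids) * 250)
  expect_equal(length(s22$token_ids) %% 8, 0)
  # every consecutive 8 tokens is a row of the inventory
  inv_keys <- apply(inv$sentences, 1, paste, collapse = ",")
  chunks <- matrix(s22$token_ids, nrow = 8)
  for (j in seq_len(ncol(chunks)))
    expect_true(paste(chunks[, j], collapse = ",") %in% inv_keys)
  # empty inventory is refused
  bad <- inv; bad$sentences <- bad$sentences[0, , drop = FALSE]
  expect_error(build_structured_sequence(bad, 1, seed = 1), "empty")
})

test_that("non-structured sequences draw tokens uniformly at random", {
  bank <- fix_bank()
  s <- build_nonstructured_sequence(bank, 32, seed = 7)
  expect_equal(sequence_duration(s), 8.0)
  s2 <- build_nonstructured_sequence(bank, 32, seed = 8)
  expect_false(identical(s$token_ids, s2$token_ids))
  # empirical token frequencies over 1e4 draws: each within 3 binomial
  # sigma of uniform
  big <- build_nonstructured_sequence(bank, 10000, seed = 9)
  counts <- table(factor(big$token_ids, levels = 1:16))
  gof <- stats::chisq.test(as.numeric(counts), p = rep(1 / 16, 16))
  expect_gt(gof$p.value, 0.001)
})

test_that("onset ramp rises monotonically from 0 to 1 and leaves the rest untouched", {
  seqn <- build_nonstructured_sequence(fix_bank(), 40, seed = 1) # 10 s
  ramped <- apply_onset_ramp(seqn, 3)
  n_ramp <- 3 * 1000
  expect_equal(ramped$waveform[1], 0)
  # gain over the ramp is monotone; samples after it are bit-identical
  gain <- ramped$waveform[2:n_ramp] / seqn$waveform[2:n_ramp]
  gain <- gain[is.finite(gain)]
  expect_true(all(diff(gain) > -1e-9))
  expect_identical(ramped$waveform[(n_ramp + 1):length(seqn$waveform)],
                   seqn$waveform[(n_ramp + 1):length(seqn$waveform)])
  # gain reaches 1 by the end of the ramp (last nonzero sample in the ramp)
  expect_lt(abs(gain[length(gain)] - 1), 1e-3)
  expect_error(apply_onset_ramp(seqn, 10), "shorter")
})

test_that("sliding RMS envelope matches analytic and brute-force oracles", {
  sr <- 1000
  # constant-amplitude sinusoid, f >> 1/window: envelope ~ a/sqrt(2)
  a <- 0.3
  x <- a * sin(2 * pi * 100 * (0:4999) / sr)
  env <- extract_envelope(x, sr, 0.010)
  interior <- env[100:4900]
  expect_true(all(abs(interior - a / sqrt(2)) < 0.01 * a))
  # zero in, zero out
  expect_equal(extract_envelope(numeric(100), sr), numeric(100))
  # square-gated tone: transitions confined to +-window of the gate edges,
  # and the whole envelope equals a literal sliding-window oracle
  gate <- rep(c(0, 1, 0), c(400, 400, 400))
  y <- gate * sin(2 * pi * 125 * (0:1199) / sr)
  env_y <- extract_envelope(y, sr, 0.010)
  w <- 10
  left <- (w - 1) %/% 2; right <- w - 1 - left
  yp <- c(rev(y[seq_len(left) + 1]), y, rev(y[length(y) - seq_len(right)]))
  oracle <- vapply(seq_along(y), function(i) sqrt(mean(yp[i:(i + w - 1)]^2)), 0)
  expect_equal(env_y, oracle, tolerance = 1e-12)
  expect_true(all(env_y[1:(400 - w)] < 1e-12))
  expect_true(all(abs(env_y[(400 + w):(800 - w)]) > 0.5))
  expect_error(extract_envelope(x, sr, 0.001), "at least 2")
})

test_that("modulation spectrum has the 0.125 Hz grid and satisfies Parseval", {
  env <- fix_nonstructured_seq()$envelope
  ms <- modulation_spectrum(env, 1000, 8)
  expect_equal(ms$freqs[2] - ms$freqs[1], 0.125)
  expect_true(all(ms$power >= 0))
  expect_equal(ms$n_segments, floor(length(env) / 8000))
  # Parseval on a single segment: energy reconstructed from the one-sided
  # magnitude spectrum equals the time-domain energy
  seg <- env[1:8000]
  ms1 <- modulation_spectrum(seg, 1000, 8)
  ns <- 8000
  e_spec <- ns * (ms1$power[1]^2 + 2 * sum(ms1$power[2:(ns / 2)]^2) +
                    ms1$power[ns / 2 + 1]^2)
  expect_equal(e_spec, sum(seg^2), tolerance = 1e-6)
  expect_error(modulation_spectrum(env[1:100], 1000, 8), "shorter")
})

test_that("tag rates appear in the modulation spectrum as the paradigm requires", {
  ms_ns <- modulation_spectrum(fix_nonstructured_seq())
  ms_st <- modulation_spectrum(fix_structured_seq())
  # largest non-DC peak at the 4 Hz syllable rate in both conditions
  expect_equal(ms_peak_frequency(ms_ns), 4)
  expect_equal(ms_peak_frequency(ms_st), 4)
  # 4 Hz bin at least 10x the mean of the four flanking bins
  flank_ratio <- function(ms) {
    i <- which.min(abs(ms$freqs - 4))
    ms$power[i] / mean(ms$power[c(i - 2, i - 1, i + 1, i + 2)])
  }
  expect_gt(flank_ratio(ms_ns), 10)
  expect_gt(flank_ratio(ms_st), 10)
  # Structured only: a 2 Hz local peak exceeding its 2 neighbors per side
  i2 <- which.min(abs(ms_st$freqs - 2))
  expect_true(all(ms_st$power[i2] > ms_st$power[c(i2 - 2, i2 - 1, i2 + 1, i2 + 2)]))
  expect_gt(ms_local_peak_excess(ms_st, 2), 0)
  expect_lt(ms_local_peak_excess(ms_ns, 2), ms_local_peak_excess(ms_st, 2))
  # no local peaks at the phrase (1 Hz) or sentence (0.5 Hz) rates:
  # the excess there is negligible against the 2 Hz word-rate excess
  expect_lt(abs(ms_local_peak_excess(ms_st, 1)), 0.05 * ms_local_peak_excess(ms_st, 2))
  expect_lt(abs(ms_local_peak_excess(ms_st, 0.5)), 0.05 * ms_local_peak_excess(ms_st, 2))
})

test_that("conditions differ only in syllable order", {
  bank <- fix_bank()
  inv <- fix_inventory()
  st <- build_structured_sequence(inv, 30, seed = 21)
  ns <- build_nonstructured_sequence(bank, 240, seed = 22)
  expect_equal(sequence_duration(st), sequence_duration(ns))
  rms_st <- sqrt(mean(st$waveform^2)); rms_ns <- sqrt(mean(ns$waveform^2))
  expect_lt(abs(rms_st - rms_ns) / rms_ns, 0.01)
  # word-rate acoustic confound: Structured 2 Hz power exceeds
  # Non-Structured in paired replicates (sign test, 20 matched seeds)
  wins <- vapply(1:20, function(k) {
    b <- make_syllable_bank(16, 1000, seed = 100 + k)
    iv <- make_sentence_inventory(b, 12, seed = 200 + k)
    p2 <- function(ms) ms$power[which.min(abs(ms$freqs - 2))]
    p2(modulation_spectrum(build_structured_sequence(iv, 32, seed = 300 + k))) >
      p2(modulation_spectrum(build_nonstructured_sequence(b, 256, seed = 400 + k)))
  }, TRUE)
  expect_lt(stats::binom.test(sum(wins), 20, 0.5, alternative = "greater")$p.value,
            0.05)
})

test_that("ramped sequences drop the ramp before spectral analysis", {
  seqn <- build_structured_sequence(fix_inventory(), 12, seed = 5) # 24 s
  ramped <- apply_onset_ramp(seqn, 3)
  ms <- modulation_spectrum(ramped)
  # 21 s remain after the ramp -> 2 full 8 s segments
  expect_equal(ms$n_segments, 2)
})

test_that("WAV output is a well-formed 16-bit PCM RIFF file", {
  seqn <- build_nonstructured_sequence(fix_bank(), 8, seed = 1)
  path <- withr::local_tempfile(fileext = ".wav")
  write_sequence_wav(seqn, path)
  con <- file(path, "rb")
  on.exit(close(con))
  expect_identical(readChar(con, 4), "RIFF")
  invisible(readBin(con, integer(), 1, 4, endian = "little"))
  expect_identical(readChar(con, 4), "WAVE")
  expect_equal(file.size(path), 44 + 2 * length(seqn$waveform))
})
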