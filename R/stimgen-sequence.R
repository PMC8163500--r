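## Stimulus sequences --------------------------------------------------------
##
## Sequences are isochronous streams of 250 ms syllable tokens (4 Hz).
## In Structured sequences every two syllables form a word (2 Hz), every
## two words a phrase (1 Hz) and every two phrases a sentence (0.5 Hz);
## sentences come from a fixed inventory. Non-Structured sequences present
## the same tokens in a fully random order. The two conditions therefore
## share all low-level acoustics and differ only in syllable order.

TAG_RATES <- c(syllable = 4, word = 2, phrase = 1, sentence = 0.5)

#' Build a fixed inventory of eight-syllable sentences
#'
#' Each sentence has 8 token slots (4 words of 2 syllables). Word-initial
#' slots (positions 1, 3, 5, 7) draw from the bank's onset-class tokens and
#' word-final slots from the coda class, mirroring natural phonotactics in
#' which different syllable subsets occur word-initially versus word-finally.
#' The inventory is balanced: every same-parity position uses a permutation
#' of the same token multiset, so averaged over the inventory the envelope
#' is exactly periodic at the word rate and carries no phrase- (1 Hz) or
#' sentence-rate (0.5 Hz) acoustic component.
#'
#' @param bank a `syllable_bank`.
#' @param n_sentences inventory size (default 12).
#' @param seed integer seed.
#' @return object of class `sentence_inventory` wrapping an
#'   `n_sentences x 8` matrix of token ids and the bank.
#' @export
make_sentence_inventory <- function(bank, n_sentences = 12, seed = 1) {
  stop_if_not(inherits(bank, "syllable_bank"), "`bank` must be a syllable_bank")
  stop_if_not(is_count(n_sentences), "`n_sentences` must be a positive integer")
  onset_ids <- token_ids_of_class(bank, "onset")
  coda_ids <- token_ids_of_class(bank, "coda")
  stop_if_not(length(onset_ids) >= 1 && length(coda_ids) >= 1,
              "bank must contain both onset- and coda-class tokens")
  with_seed(seed, {
    s_a <- sample(onset_ids, n_sentences, replace = n_sentences > length(onset_ids))
    s_b <- sample(coda_ids, n_sentences, replace = n_sentences > length(coda_ids))
    mat <- matrix(0L, n_sentences, 8L)
    for (p in c(1L, 3L, 5L, 7L)) mat[, p] <- sample(s_a)
    for (p in c(2L, 4L, 6L, 8L)) mat[, p] <- sample(s_b)
  })
  structure(list(sentences = mat, bank = bank, seed = seed),
            class = "sentence_inventory")
}

#' Build a Structured frequency-tagged sequence
#'
#' Draws `n_sentences` sentences (with replacement, seeded) from a fixed
#' inventory and concatenates their tokens with no acoustic gaps, so the
#' linguistic levels sit at fixed rates: syllables 4 Hz, words 2 Hz,
#' phrases 1 Hz, sentences 0.5 Hz.
#'
#' @param inventory a `sentence_inventory`.
#' @param n_sentences number of sentences in the sequence (>= 1).
#' @param seed integer seed for the sentence draws.
#' @return a `stimulus_sequence` (see [render_sequence()]).
#' @export
build_structured_sequence <- function(inventory, n_sentences, seed = 1) {
  stop_if_not(inherits(inventory, "sentence_inventory"),
              "`inventory` must be a sentence_inventory")
  stop_if_not(nrow(inventory$sentences) >= 1, "empty sentence inventory")
  stop_if_not(is_count(n_sentences), "`n_sentences` must be a positive integer")
  draws <- with_seed(seed, sample.int(nrow(inventory$sentences), n_sentences,
                                      replace = TRUE))
  token_ids <- as.integer(t(inventory$sentences[draws, , drop = FALSE]))
  render_sequence(inventory$bank, token_ids, condition = "Structured")
}

#' Build a Non-Structured (random-order) sequence
#'
#' Tokens are drawn uniformly at random from the whole bank with no
#' constraint tying tokens to within-word positions; the syllable rate
#' (4 Hz) is the only tagged rate.
#'
#' @param bank a `syllable_bank`.
#' @param n_syllables number of syllables (>= 1).
#' @param seed integer seed.
#' @return a `stimulus_sequence`.
#' @export
build_nonstructured_sequence <- function(bank, n_syllables, seed = 1) {
  stop_if_not(inherits(bank, "syllable_bank"), "`bank` must be a syllable_bank")
  stop_if_not(is_count(n_syllables), "`n_syllables` must be a positive integer")
  ids <- vapply(bank$tokens, `[[`, 0L, "token_id")
  token_ids <- with_seed(seed, sample(ids, n_syllables, replace = TRUE))
  render_sequence(bank, token_ids, condition = "NonStructured")
}

#' Render a token-id sequence into waveform and envelope
#'
#' @param bank a `syllable_bank`.
#' @param token_ids ordered token ids.
#' @param condition `"Structured"` or `"NonStructured"`.
#' @return an object of class `stimulus_sequence` with fields `condition`,
#'   `token_ids`, `waveform`, `envelope` (10 ms sliding RMS), `sample_rate`,
#'   `tag_rates` and `onset_ramp_dur` (0 until [apply_onset_ramp()] is used).
#' @export
render_sequence <- function(bank, token_ids, condition) {
  condition <- match.arg(condition, c("Structured", "NonStructured"))
  idx <- match(token_ids, vapply(bank$tokens, `[[`, 0L, "token_id"))
  stop_if_not(!anyNA(idx), "unknown token id in `token_ids`")
  waveform <- unlist(lapply(bank$tokens[idx], `[[`, "waveform"), use.names = FALSE)
  structure(list(condition = condition,
                 token_ids = as.integer(token_ids),
                 waveform = waveform,
                 envelope = extract_envelope(waveform, bank$sample_rate),
                 sample_rate = bank$sample_rate,
                 tag_rates = TAG_RATES,
                 onset_ramp_dur = 0),
            class = "stimulus_sequence")
}

#' Sequence duration in seconds
#' @param seq a `stimulus_sequence`.
#' @export
sequence_duration <- function(seq) length(seq$waveform) / seq$sample_rate

#' Apply a gradual intensity onset ramp
#'
#' Multiplies the waveform by a monotone raised-cosine gain rising from 0
#' at t = 0 to 1 at `ramp_dur`; later samples are untouched. This mirrors
#' the gradual fade-in used to avoid giving away word boundaries at trial
#' start; analyses discard the ramped portion.
#'
#' @param seq a `stimulus_sequence`.
#' @param ramp_dur ramp duration in seconds (default 3, must be shorter
#'   than the sequence).
#' @return the ramped `stimulus_sequence` with `onset_ramp_dur` set.
#' @export
apply_onset_ramp <- function(seq, ramp_dur = 3) {
  stop_if_not(inherits(seq, "stimulus_sequence"), "`seq` must be a stimulus_sequence")
  stop_if_not(is_scalar_num(ramp_dur) && ramp_dur > 0, "`ramp_dur` must be > 0")
  dur <- sequence_duration(seq)
  stop_if_not(ramp_dur < dur, "`ramp_dur` (%g s) must be shorter than the sequence (%g s)",
              ramp_dur, dur)
  n <- length(seq$waveform)
  nr <- round(ramp_dur * seq$sample_rate)
  t <- (seq_len(nr) - 1L) / nr
  gain <- c(sin(pi / 2 * t)^2, rep(1, n - nr))
  seq$waveform <- seq$waveform * gain
  seq$envelope <- extract_envelope(seq$waveform, seq$sample_rate)
  seq$onset_ramp_dur <- ramp_dur
  seq
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf("%s sequence: %d syllables, %.2f s @ %g Hz (onset ramp %g s)\n",
              x$condition, length(x$token_ids), sequence_duration(x),
              x$sample_rate, x$onset_ramp_dur))
  invisible(x)
}

#' Write a sequence as 16-bit PCM mono WAV
#'
#' Minimal RIFF/WAVE writer (no audio package is required at run time).
#' Samples are scaled so the waveform peak maps to 90% full scale.
#'
#' @param seq a `stimulus_sequence`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sequence_wav <- function(seq, path) {
  stop_if_not(inherits(seq, "stimulus_sequence"), "`seq` must be a stimulus_sequence")
  x <- seq$waveform
  peak <- max(abs(x), 1e-12)
  pcm <- as.integer(round(x / peak * 0.9 * 32767))
  sr <- as.integer(round(seq$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # PCM
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little")  # block align
  writeBin(16L, con, size = 2, endian = "little") # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
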