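## Broadband envelope and modulation spectrum --------------------------------

#' Extract the broadband RMS envelope of a waveform
#'
#' Centered sliding root-mean-square with a 10 ms window (reflect padding
#' at the edges, so the first bins carry no spurious onset transient). The
#' output has the same length as the input.
#'
#' @param waveform numeric audio samples (non-empty).
#' @param sample_rate sample rate in Hz.
#' @param window smoothing window in seconds (default 0.010).
#' @return non-negative numeric vector, same length as `waveform`.
#' @export
extract_envelope <- function(waveform, sample_rate, window = 0.010) {
  stop_if_not(is.numeric(waveform) && length(waveform) > 0,
              "`waveform` must be a non-empty numeric vector")
  w <- round(window * sample_rate)
  stop_if_not(w >= 2, "smoothing window must span at least 2 samples")
  sqrt(pmax(moving_average_reflect(waveform^2, w), 0))
}

#' Modulation spectrum of an amplitude envelope
#'
#' The spectral procedure applied to stimuli is deliberately identical to
#' the one applied to neural recordings: the envelope is cut into
#' non-overlapping 8 s segments from the start, each segment is Fourier
#' transformed without tapering, and FFT magnitudes are averaged across
#' segments. The frequency grid spacing is `1/segment_dur` (0.125 Hz for
#' 8 s segments), which places all tag rates exactly on bins.
#'
#' For a `stimulus_sequence` with an onset ramp applied, the ramped portion
#' is discarded before segmentation, matching the exclusion of trial starts
#' from analysis.
#'
#' @param x numeric envelope vector, or a `stimulus_sequence`.
#' @param sample_rate sample rate in Hz (ignored for sequences).
#' @param segment_dur segment duration in seconds (default 8).
#' @return object of class `modulation_spectrum` with fields `freqs` (Hz,
#'   0 to Nyquist), `power` (mean FFT magnitude per bin), `n_segments` and
#'   `segment_dur`.
#' @export
modulation_spectrum <- function(x, sample_rate = NULL, segment_dur = 8) {
  UseMethod("modulation_spectrum")
}

#' @export
modulation_spectrum.stimulus_sequence <- function(x, sample_rate = NULL,
                                                  segment_dur = 8) {
  env <- x$envelope
  if (x$onset_ramp_dur > 0) {
    drop <- round(x$onset_ramp_dur * x$sample_rate)
    env <- env[-seq_len(drop)]
  }
  modulation_spectrum(env, x$sample_rate, segment_dur)
}

#' @export
modulation_spectrum.default <- function(x, sample_rate = NULL, segment_dur = 8) {
  stop_if_not(is.numeric(x) && length(x) > 0, "`x` must be a numeric envelope")
  stop_if_not(is_scalar_num(sample_rate), "`sample_rate` is required")
  ns <- round(segment_dur * sample_rate)
  n_seg <- floor(length(x) / ns)
  stop_if_not(n_seg >= 1,
              "envelope (%.2f s) shorter than one %g s segment",
              length(x) / sample_rate, segment_dur)
  segs <- matrix(x[seq_len(n_seg * ns)], nrow = ns)
  mags <- abs(stats::mvfft(segs)) / ns
  half <- seq_len(ns %/% 2 + 1L)
  structure(list(freqs = (half - 1L) / segment_dur,
                 power = rowMeans(mags[half, , drop = FALSE]),
                 n_segments = n_seg,
                 segment_dur = segment_dur),
            class = "modulation_spectrum")
}

#' @export
print.modulation_spectrum <- function(x, ...) {
  cat(sprintf("modulation spectrum: %d segments of %g s, %g Hz resolution\n",
              x$n_segments, x$segment_dur, 1 / x$segment_dur))
  invisible(x)
}

#' Frequency of the largest non-DC modulation peak
#'
#' @param ms a `modulation_spectrum`.
#' @param exclude_at_or_below bins at or below this frequency (Hz) are
#'   excluded (default 0.125, i.e. DC and the first bin).
#' @return frequency in Hz.
#' @export
ms_peak_frequency <- function(ms, exclude_at_or_below = 0.125) {
  keep <- ms$freqs > exclude_at_or_below
  ms$freqs[keep][which.max(ms$power[keep])]
}

#' Local peak excess at a frequency bin
#'
#' Power at the bin nearest `freq` minus the mean power of `n_flank`
#' neighboring bins on each side. Positive values indicate a local peak.
#'
#' @param ms a `modulation_spectrum`.
#' @param freq frequency in Hz.
#' @param n_flank flanking bins per side (default 2).
#' @return numeric excess (same units as `power`).
#' @export
ms_local_peak_excess <- function(ms, freq, n_flank = 2) {
  i <- which.min(abs(ms$freqs - freq))
  stop_if_not(i - n_flank >= 1 && i + n_flank <= length(ms$freqs),
              "not enough flanking bins around %g Hz", freq)
  flank <- c(i - seq_len(n_flank), i + seq_len(n_flank))
  ms$power[i] - mean(ms$power[flank])
}

#' Write a modulation spectrum as TSV
#'
#' Columns: `freq_hz`, `power`, `condition`.
#'
#' @param ms a `modulation_spectrum`.
#' @param path output path.
#' @param condition condition label to record.
#' @return `path`, invisibly.
#' @export
write_modulation_spectrum_tsv <- function(ms, path, condition = NA_character_) {
  df <- data.frame(freq_hz = ms$freqs, power = ms$power, condition = condition)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
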