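## Segmentation and inter-trial phase coherence ------------------------------

#' Segment trial recordings into tag-aligned 8 s epochs
#'
#' Each trial is cut into non-overlapping `segment_dur` segments starting
#' at the first syllable onset (250 ms grid) at or after `exclude_initial`
#' seconds. Segments step by a whole number of sentences, so all segments
#' share the same fixed offset within the sentence cycle and phase
#' coherence at every tag rate is preserved (ITPC is invariant to a common
#' phase offset). Partial trailing segments are dropped; the ramped trial
#' start is excluded from analysis.
#'
#' @param recordings list of `trial_recording`s from one participant and
#'   one condition.
#' @param exclude_initial seconds excluded at trial start (default 3).
#' @param segment_dur segment duration in seconds (default 8).
#' @return object of class `segment_set`: `segments` is an array
#'   `n_segments x channels x samples`; also carries `segment_dur`,
#'   `sample_rate`, `participant_id`, `condition`.
#' @export
segment_trials <- function(recordings, exclude_initial = 3, segment_dur = 8) {
  if (inherits(recordings, "trial_recording")) recordings <- list(recordings)
  stop_if_not(length(recordings) >= 1, "`recordings` must be non-empty")
  stop_if_not(all(vapply(recordings, inherits, TRUE, "trial_recording")),
              "`recordings` must be trial_recording objects")
  conds <- unique(vapply(recordings, `[[`, "", "condition"))
  pids <- unique(vapply(recordings, function(r) as.integer(r$participant_id), 0L))
  stop_if_not(length(conds) == 1L, "recordings mix conditions: %s",
              paste(conds, collapse = ", "))
  sr <- recordings[[1]]$sample_rate
  ns <- round(segment_dur * sr)
  syllable_step <- round(0.25 * sr)
  seg_list <- list()
  for (r in recordings) {
    n <- ncol(r$data)
    # first syllable onset at or after the excluded window
    k0 <- ceiling(max(exclude_initial * sr - (r$tag_onset_index - 1), 0) / syllable_step)
    start <- r$tag_onset_index + k0 * syllable_step
    n_seg <- floor((n - start + 1) / ns)
    stop_if_not(n_seg >= 1,
                "trial %s of participant %s too short: %.2f s after excluding %g s",
                r$trial_id, r$participant_id, n / sr, exclude_initial)
    for (j in seq_len(n_seg)) {
      idx <- start + (j - 1L) * ns + seq_len(ns) - 1L
      seg_list[[length(seg_list) + 1L]] <- r$data[, idx, drop = FALSE]
    }
  }
  m <- length(seg_list)
  segs <- array(0, dim = c(m, nrow(seg_list[[1]]), ns))
  for (i in seq_len(m)) segs[i, , ] <- seg_list[[i]]
  structure(list(segments = segs, segment_dur = segment_dur, sample_rate = sr,
                 alignment = "syllable_onset",
                 participant_id = if (length(pids) == 1L) pids else NA_integer_,
                 condition = conds),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  d <- dim(x$segments)
  cat(sprintf("segment_set: %d segments x %d channels x %d samples (%s, %s)\n",
              d[1], d[2], d[3], x$condition, x$alignment))
  invisible(x)
}

#' Inter-trial phase coherence spectrum (Rayleigh z)
#'
#' For every channel and frequency bin, the phase of the un-tapered FFT of
#' each 8 s segment is extracted and the Rayleigh statistic computed:
#' `z = m * Rbar^2`, where `Rbar` is the mean resultant length of the `m`
#' segment phases. This is the normalized (z-scored) ITPC: it is bounded
#' by `m` (perfect phase locking) and has expectation ~1 under uniformly
#' random phases. Tagged frequencies fall exactly on the 1/8 = 0.125 Hz
#' FFT grid, so no taper is applied.
#'
#' @param segs a `segment_set` with at least 2 segments.
#' @param freq_max top of the frequency grid in Hz (default 15).
#' @return object of class `itpc_spectrum`: `freqs` (0.125 Hz steps),
#'   `z` (channels x freqs), `n_segments`.
#' @export
compute_itpc <- function(segs, freq_max = 15) {
  stop_if_not(inherits(segs, "segment_set"), "`segs` must be a segment_set")
  d <- dim(segs$segments)
  m <- d[1]; n_chan <- d[2]; ns <- d[3]
  stop_if_not(m >= 2, "ITPC needs at least 2 segments (got %d)", m)
  df <- 1 / segs$segment_dur
  k_max <- min(floor(freq_max / df), ns %/% 2)
  bins <- seq_len(k_max) + 1L # FFT bins for df, 2*df, ...
  z <- matrix(0, n_chan, k_max)
  for (c in seq_len(n_chan)) {
    X <- stats::mvfft(t(segs$segments[, c, ]))   # ns x m
    ph <- X[bins, , drop = FALSE]
    ph <- ph / pmax(abs(ph), .Machine$double.xmin) # unit phasors
    z[c, ] <- m * (abs(rowSums(ph)) / m)^2
  }
  structure(list(freqs = seq_len(k_max) * df, z = z, n_segments = m,
                 participant_id = segs$participant_id,
                 condition = segs$condition),
            class = "itpc_spectrum")
}

#' @export
print.itpc_spectrum <- function(x, ...) {
  cat(sprintf("itpc_spectrum: %d channels, %g-%g Hz (%g Hz step), %d segments\n",
              nrow(x$z), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1], x$n_segments))
  invisible(x)
}

#' Average an ITPC spectrum across channels
#'
#' The scalp-level statistic averages Rayleigh z across channels (or a
#' channel subset) *before* any group-level test, avoiding per-channel
#' multiple comparisons.
#'
#' @param spec an `itpc_spectrum`.
#' @param channels channel indices (default all).
#' @return named numeric vector of z values, one per frequency.
#' @export
channel_average <- function(spec, channels = NULL) {
  stop_if_not(inherits(spec, "itpc_spectrum"), "`spec` must be an itpc_spectrum")
  if (is.null(channels)) channels <- seq_len(nrow(spec$z))
  out <- colMeans(spec$z[channels, , drop = FALSE])
  names(out) <- spec$freqs
  out
}

#' Stack per-participant channel-averaged spectra into a matrix
#'
#' @param spectra list of `itpc_spectrum` objects (one per participant).
#' @param channels optional channel subset.
#' @return participants x frequencies matrix with a `freqs` attribute.
#' @export
spectra_matrix <- function(spectra, channels = NULL) {
  stop_if_not(length(spectra) >= 1, "`spectra` must be non-empty")
  mat <- do.call(rbind, lapply(spectra, channel_average, channels = channels))
  attr(mat, "freqs") <- spectra[[1]]$freqs
  mat
}

#' Peak test at a frequency of interest
#'
#' Paired t-test across participants of the ITPC at the frequency of
#' interest against the mean of the flanking bins (`n_neighbor_bins` per
#' side), the standard frequency-tagging peak statistic. Two-sided.
#'
#' @param spectra participants x frequencies matrix with a `freqs`
#'   attribute (see [spectra_matrix()]), or a list of `itpc_spectrum`s.
#' @param foi frequency of interest in Hz (must lie on the grid with at
#'   least `n_neighbor_bins` bins on each side).
#' @param n_neighbor_bins flanking bins per side (default 2).
#' @return object of class `foi_test`: `foi`, `t`, `df`, `p`, `cohen_d`,
#'   and the per-participant `foi_values` and `neighbor_values`.
#' @export
foi_peak_test <- function(spectra, foi, n_neighbor_bins = 2) {
  if (!is.matrix(spectra)) spectra <- spectra_matrix(spectra)
  freqs <- attr(spectra, "freqs")
  stop_if_not(!is.null(freqs), "`spectra` must carry a `freqs` attribute")
  i <- which(abs(freqs - foi) < 1e-9)
  stop_if_not(length(i) == 1L, "`foi` = %g Hz is not on the frequency grid", foi)
  stop_if_not(i - n_neighbor_bins >= 1 && i + n_neighbor_bins <= length(freqs),
              "not enough neighbor bins around %g Hz", foi)
  flank <- c(i - seq_len(n_neighbor_bins), i + seq_len(n_neighbor_bins))
  v_foi <- spectra[, i]
  v_nb <- rowMeans(spectra[, flank, drop = FALSE])
  d <- v_foi - v_nb
  n <- length(d)
  t <- t_stat(d)
  p <- if (stats::sd(d) == 0) 1 else 2 * stats::pt(-abs(t), df = n - 1)
  structure(list(foi = foi, t = t, df = n - 1L, p = p,
                 cohen_d = cohens_d(d),
                 foi_values = v_foi, neighbor_values = v_nb),
            class = "foi_test")
}

#' @export
print.foi_test <- function(x, ...) {
  cat(sprintf("FOI %g Hz: t(%d) = %.3f, p = %.4g, Cohen's d = %.2f\n",
              x$foi, x$df, x$t, x$p, x$cohen_d))
  invisible(x)
}

#' Write per-participant ITPC spectra as TSV
#'
#' Columns: `participant`, `condition`, `channel_set`, `freq_hz`, `z`.
#'
#' @param spectra list of `itpc_spectrum`s.
#' @param path output path.
#' @param channel_set label for the averaged channel set.
#' @param channels optional channel subset to average.
#' @return `path`, invisibly.
#' @export
write_itpc_tsv <- function(spectra, path, channel_set = "all", channels = NULL) {
  rows <- do.call(rbind, lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    data.frame(participant = s$participant_id, condition = s$condition,
               channel_set = channel_set, freq_hz = s$freqs,
               z = as.numeric(channel_average(s, channels)))
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
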