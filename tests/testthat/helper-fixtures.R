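# Shared fixtures, built once per test run. All fixtures are generated in
# code from fixed seeds; nothing is read from disk.

fixture_env <- new.env()

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

fix_bank <- function() fixture("bank", function() make_syllable_bank(16, 1000, seed = 1))
fix_inventory <- function() fixture("inventory", function()
  make_sentence_inventory(fix_bank(), 12, seed = 2))

# Long sequences for spectral checks (>= 64 s)
fix_structured_seq <- function() fixture("structured_seq", function()
  build_structured_sequence(fix_inventory(), 40, seed = 3))
fix_nonstructured_seq <- function() fixture("nonstructured_seq", function()
  build_nonstructured_sequence(fix_bank(), 320, seed = 4))

# A small simulated participant (both conditions), cheap but realistic
fix_small_cfg <- function() fixture("small_cfg", function()
  sim_config(n_participants = 2, n_trials_per_condition = 4,
             n_sentences_per_trial = 6, seed = 11))
fix_small_trials <- function() fixture("small_trials", function()
  simulate_participant(fix_small_cfg(), 1))

# Build a trial_recording directly (for segmentation tests)
make_recording <- function(data, sample_rate = 200, condition = "Structured",
                           participant_id = 1L, trial_id = 1L) {
  structure(list(data = data, condition = condition,
                 attended_envelope = numeric(ncol(data)),
                 tag_onset_index = 1L, participant_id = participant_id,
                 trial_id = trial_id, sample_rate = sample_rate),
            class = "trial_recording")
}

# Build a segment_set directly from an array (for ITPC analytics)
make_segments <- function(segments, segment_dur = 8,
                          sample_rate = dim(segments)[3] / segment_dur) {
  structure(list(segments = segments, segment_dur = segment_dur,
                 sample_rate = sample_rate, alignment = "sentence_onset",
                 participant_id = 1L, condition = "Structured"),
            class = "segment_set")
}

# Independent flood-fill oracle for cluster identification, built on
# igraph components over the explicit (unit, bin) product graph.
oracle_clusters <- function(mask, adjacency) {
  U <- nrow(mask); B <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(list())
  edges <- list()
  for (u in seq_len(U)) for (b in seq_len(B)) {
    if (!mask[u, b]) next
    i <- (b - 1) * U + u
    if (b < B && mask[u, b + 1]) edges[[length(edges) + 1]] <- c(i, i + U)
    for (v in which(adjacency[u, ])) {
      if (v > u && mask[v, b]) edges[[length(edges) + 1]] <- c(i, (b - 1) * U + v)
    }
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, c(list(matrix(0L, 0, 2)), edges)),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, U * B - igraph::vcount(g)))
  comp <- igraph::components(g)
  groups <- split(idx, comp$membership[idx])
  lapply(unname(groups), function(m)
    cbind(unit = (m - 1) %% U + 1, bin = (m - 1) %/% U + 1))
}

# Canonical form for comparing cluster member sets
cluster_key <- function(members) {
  paste(sort(paste(members[, "unit"], members[, "bin"], sep = ":")), collapse = ";")
}
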