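# shared fixtures: reduced channel sets and quick simulated trials keep the
# unit tests fast while exercising the same code paths as the full montage

test_channels <- function() {
  c("Fz", "F3", "F4", "FC1", "FC2", "Cz", "C3", "C4", "CP1", "CP2",
    "Pz", "P5", "P6", "PO7", "PO8", "Oz")
}

test_components <- function(channels = test_channels()) {
  default_components(channels)
}

# a hand-built schedule tibble with the columns the signal path needs
fake_schedule <- function(n, target_at = integer(0), soa_ms = 166,
                          element_id = "R1", level = 1L, phase = "core",
                          sequence = 1L) {
  tibble::tibble(
    index = seq_len(n),
    onset_ms = (seq_len(n) - 1) * soa_ms,
    level = level,
    phase = phase,
    sequence = sequence,
    element_id = element_id,
    is_target = seq_len(n) %in% target_at
  )
}

# one simulated trial, reduced montage, at a modest rate
quick_trial <- function(kind = "matrix", target = "B", seed = 1, fs = 250,
                        rms = 1, modulation = modulation_profile("overt",
                                                                 kind),
                        components = test_components()) {
  layout <- build_layout(kind)
  sched <- generate_trial_schedule(layout, target, seed = seed)
  rec <- synthesize_recording(sched, components, modulation,
                              noise_model(rms_uV = rms), fs = fs,
                              seed = seed + 1000L)
  list(layout = layout, sched = sched, rec = rec)
}

# build an epoch_set directly from an epochs x channels x time array
make_epoch_set <- function(data, times_ms, channels,
                           labels = rep("target", dim(data)[1]),
                           kept = rep(TRUE, dim(data)[1]), fs = 100) {
  dimnames(data) <- list(NULL, channels, NULL)
  structure(
    list(data = data, times_ms = times_ms, channels = channels, fs = fs,
         window = epoch_window(-170, 670),
         info = tibble::tibble(
           epoch = seq_len(dim(data)[1]),
           event_index = seq_len(dim(data)[1]),
           label = labels, level = 1L, phase = "core", sequence = 1L,
           element_id = "R1", kept = kept, reason = NA_character_)),
    class = "epoch_set")
}

# brute-force reference for the target-epoch contamination rule
oracle_target_filter <- function(index, is_target, min_gap = 3) {
  pos <- index[is_target]
  kept <- logical(length(pos))
  for (i in seq_along(pos)) {
    others <- pos[-i]
    kept[i] <- all(abs(others - pos[i]) >= min_gap)
    # only nearest neighbours matter, but checking all is equivalent
  }
  pos[kept]
}

# brute-force reference for the nontarget contamination rule
oracle_nontarget_filter <- function(index, is_target, n_before = 3,
                                    n_after = 2) {
  keep <- integer(0)
  for (i in seq_along(index)) {
    if (is_target[i]) next
    bad <- FALSE
    for (j in seq_along(index)) {
      if (!is_target[j]) next
      d <- index[j] - index[i]
      if ((d < 0 && -d <= n_before) || (d > 0 && d <= n_after)) bad <- TRUE
    }
    if (!bad) keep <- c(keep, index[i])
  }
  keep
}
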