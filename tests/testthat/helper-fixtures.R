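# Shared fixture builders for the suite. Everything is generated in
# code from fixed seeds; no data files are read.

fixture_templates <- function(seed = 1, k = 4) {
  generate_templates(n_channels = 19, k = k, seed = seed)
}

# A short synthetic recording with known ground truth.
fixture_synthetic <- function(seed = 1, snr = 4, duration_s = 10,
                              dwell_ms = 60, k = 4) {
  tpl <- fixture_templates(seed, k)
  spec <- state_sequence_spec(uniform_transitions(k),
                              mean_dwell_ms = dwell_ms,
                              sampling_rate_hz = 500,
                              total_duration_s = duration_s,
                              seed = seed)
  labels <- simulate_state_sequence(spec)
  eeg <- synthesize_eeg(tpl, labels, 500, snr, seed = seed + 100L)
  list(templates = tpl, spec = spec, labels = labels, eeg = eeg)
}

# One full template-recovery run; returns alignment, accuracy and the
# temporal parameters against ground truth.
fixture_recovery_run <- function(seed, snr = 4, n_restarts = 20,
                                 duration_s = 50, min_duration_ms = 0) {
  fx <- fixture_synthetic(seed, snr = snr, duration_s = duration_s)
  eps <- epochs_from_matrix(fx$eeg$data, 500,
                            n = duration_s / 10, length_s = 10)
  pk <- microdyn:::collect_peak_maps(eps)
  model <- modified_kmeans(pk$maps, k = 4, n_restarts = n_restarts,
                           seed = seed + 200L)
  al <- microdyn:::best_alignment(fx$templates$maps, model$maps)
  seg <- backfit(eps, model, min_duration_ms = min_duration_ms)
  params <- compute_parameters(seg)
  accuracy <- mean(al$perm[fx$labels] == unlist(seg$labels))
  list(fx = fx, model = model, alignment = al, segmentation = seg,
       params = params, accuracy = accuracy,
       occupancy = stationary_occupancy(fx$spec))
}

# Pool aligned transition counts from a segmentation into truth order.
pooled_transition_counts <- function(seg, perm, k = 4) {
  counts <- matrix(0, k, k)
  segs <- seg$segments
  for (e in unique(segs$epoch)) {
    st <- segs$state[segs$epoch == e]
    if (length(st) < 2) next
    for (i in seq_len(length(st) - 1)) {
      f <- which(perm == st[i]); t2 <- which(perm == st[i + 1])
      counts[f, t2] <- counts[f, t2] + 1
    }
  }
  counts
}

make_recording <- function(mat, fs = 500) {
  eeg_recording(mat, montage_1020()$label[seq_len(nrow(mat))], fs)
}
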