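# Shared fixtures, built in code at test time.

# canonical 1 Hz / 5-beat / 100 FPS reference recording
std_spec <- function(...) {
  args <- modifyList(list(pacing_hz = 1, n_beats = 5, fps = 100,
                          baseline = 100, magnitude = 100,
                          tau_on = 30, tau_off = 300, latency_ms = 100,
                          seed = 1L), list(...))
  do.call(waveform_spec, args)
}

std_config <- function(...) {
  args <- modifyList(list(pacing_hz = 1), list(...))
  do.call(ca_config, args)
}

# best Jaccard overlap of a ground-truth footprint with any accepted region
best_jaccard <- function(truth_fp, mask) {
  labs <- mask$props$label[mask$props$accepted]
  if (length(labs) == 0) return(0)
  max(vapply(labs, function(lab) {
    rf <- mask$label_image == lab
    sum(truth_fp & rf) / sum(truth_fp | rf)
  }, numeric(1)))
}

# score a segmented multi-cell field against its generator ground truth
score_field <- function(field, mask, jaccard_min = 0.5) {
  truth <- field$truth
  n_rod <- length(truth$specs)
  rod_hits <- sum(vapply(seq_len(n_rod), function(k) {
    best_jaccard(truth$label_image == k, mask) > jaccard_min
  }, logical(1)))
  ndead <- max(truth$dead_label_image)
  dead_ids <- Filter(function(k) sum(truth$dead_label_image == k) > 0,
                     seq_len(ndead))
  dead_hits <- sum(vapply(dead_ids, function(k) {
    df <- truth$dead_label_image == k
    labs <- mask$props$label[mask$props$accepted]
    any(vapply(labs, function(lab) {
      rf <- mask$label_image == lab
      sum(df & rf) / sum(df) > jaccard_min
    }, logical(1)))
  }, logical(1)))
  n_accepted <- sum(mask$props$accepted)
  list(n_rod = n_rod, rod_hits = rod_hits,
       n_dead = length(dead_ids), dead_hits = dead_hits,
       false_pos = max(0, n_accepted - rod_hits - dead_hits))
}

# brute-force crossing time: 1000x-oversampled linear interpolation of the
# sampled trace, first grid crossing refined linearly (independent of the
# analysis interpolation routines)
brute_rise_crossing_ms <- function(v, ip, thr, fps, oversample = 1000) {
  t <- (seq_len(ip) - 1) / fps * 1000
  tg <- seq(t[1], t[ip], length.out = (ip - 1) * oversample + 1)
  vg <- approx(t, v[seq_len(ip)], xout = tg)$y
  i <- which(vg[-length(vg)] < thr & vg[-1] >= thr)[1]
  if (is.na(i)) return(NA_real_)
  tg[i] + (tg[i + 1] - tg[i]) * (thr - vg[i]) / (vg[i + 1] - vg[i])
}
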