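# Shared fixtures: beats are built in code, never stored on disk.

# Build a beat from per-lead c(q, r, s) or c(q, r, s, qrsd) vectors;
# unspecified leads are flat with a 100 ms duration.
make_beat <- function(..., beat_type = "pvc") {
  given <- list(...)
  leads <- lapply(ECG_LEADS, function(ld) {
    v <- given[[ld]]
    if (is.null(v)) v <- c(0, 0, 0)
    if (length(v) == 3) v <- c(v, 100)
    lead_wave(v[1], v[2], v[3], v[4])
  })
  names(leads) <- ECG_LEADS
  beat_measurement(beat_type, leads)
}

# Group-median PVC beat assembled from the shipped quartile table.
median_beat <- function(group) {
  path <- system.file("extdata", "ecg_amplitude_quartiles.csv",
                      package = "pvcorigin")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$group == group, ]
  leads <- lapply(ECG_LEADS, function(ld) {
    g <- function(w) df$q50[df$lead == ld & df$wave == w]
    lead_wave(g("q"), g("r"), g("s"), g("qrsd"))
  })
  names(leads) <- ECG_LEADS
  beat_measurement("pvc", leads)
}

# Small reproducible labeled cohort from the packaged models.
small_cohort <- function(n_srvot = 12, n_lvot = 8, seed = 7, rho = 0.3) {
  m <- outflow_group_models(rho = rho)
  generate_cohort(m$srvot, m$lvot_asc, n_srvot, n_lvot, seed = seed)
}

# Brute-force AUC by pair counting (ties count one half).
bf_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}

# Exhaustive Youden search under the strict ">" rule over observed
# thresholds; returns the maximal J.
bf_youden_j <- function(scores, pos) {
  best <- -Inf
  for (t in sort(unique(scores))) {
    pred <- scores > t
    j <- sum(pred & pos) / sum(pos) + sum(!pred & !pos) / sum(!pos) - 1
    best <- max(best, j)
  }
  best
}
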