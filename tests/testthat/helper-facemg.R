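# Shared fixtures and oracles, all built in code.

# modulation with every scene factor 1 and all noise sources off
identity_modulation <- function() {
  modulation_spec(cs_scene = rep(1, 4), oo_scene = rep(1, 4),
                  cs_attractiveness_shift = 0,
                  cs_actor_gender_scene4_shift = 0,
                  responsiveness_sd = 0, trial_noise_sd = 0)
}

# no mains, no artifacts
clean_nuisance <- function() {
  nuisance_spec(mains_amp = c(`50` = 0, `100` = 0, `150` = 0),
                artifact_prob = 0)
}

# synthesize + preprocess a set of participants, returning the trial-scene table
run_participants <- function(design, modulation, nuisance, n = NULL,
                             channels = c("CS", "OO"), artifact_k = 8) {
  pids <- unique(design$events$participant)
  if (!is.null(n)) pids <- pids[seq_len(n)]
  dplyr::bind_rows(lapply(pids, function(p) {
    rec <- synthesize_recording(design, modulation, nuisance, p,
                                channels = channels)
    preprocess_recording(rec, design, channels = channels,
                         artifact_k = artifact_k)
  }))
}

# independent mixed-ANOVA oracle: stats::aov with an Error() stratum per
# within-effect, compared by sorted effect-name key
aov_oracle_f <- function(tab, dv = "mean_rel") {
  d <- as.data.frame(tab)
  for (v in c("participant", "participant_gender", "perspective",
              "actor_gender", "attractiveness", "scene")) {
    if (v %in% names(d)) d[[v]] <- factor(d[[v]])
  }
  form <- stats::as.formula(paste(
    dv, "~ participant_gender*perspective*actor_gender*attractiveness*scene",
    "+ Error(participant/(perspective*actor_gender*attractiveness*scene))"))
  s <- summary(stats::aov(form, data = d))
  ref <- do.call(rbind, lapply(s, function(st) {
    df <- st[[1]]
    data.frame(effect = trimws(rownames(df)), f = df[["F value"]])
  }))
  ref <- ref[!is.na(ref$f), ]
  ref$key <- vapply(ref$effect, normalize_effect_key, "")
  ref
}

normalize_effect_key <- function(e) {
  paste(sort(strsplit(e, ":", fixed = TRUE)[[1]]), collapse = ":")
}

# hand-rolled Benjamini-Hochberg step-up, used as the oracle for adjusted p
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# band power fraction via periodogram
band_power_fraction <- function(x, rate, lo, hi) {
  spec <- Mod(stats::fft(x - mean(x)))^2
  n <- length(x)
  freqs <- (seq_len(n) - 1) * rate / n
  half <- freqs <= rate / 2
  in_band <- half & freqs >= lo & freqs <= hi
  sum(spec[in_band]) / sum(spec[half])
}
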