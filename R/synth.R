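#' Ground-truth envelope modulation specification
#'
#' Describes how the rectified-envelope amplitude of each muscle departs from
#' its fixation baseline during the four movie scenes. A factor of 1 means "no
#' change from baseline"; the recovered baseline-relative scene mean of the
#' processing chain estimates exactly this factor. The default factors emulate
#' the corrugator supercilii (CS) scene profile rising from about 1.03 to 1.10
#' across the four scenes with a small attractiveness shift and an
#' actor-gender difference confined to the pain-expression scene, and an
#' orbicularis oculi (OO) profile flat near 1 with a rise in the final scene.
#'
#' @param baseline_amp expected rectified-envelope amplitude (microvolts)
#'   during fixation, named per muscle.
#' @param cs_scene,oo_scene length-4 baseline-relative scene factors for the
#'   CS and OO channels.
#' @param cs_attractiveness_shift half-difference added to every CS scene
#'   factor for low-attractiveness actors and subtracted for
#'   high-attractiveness actors.
#' @param cs_actor_gender_scene4_shift half-difference added to the CS
#'   scene-4 factor for female actors and subtracted for male actors.
#' @param responsiveness_sd log-scale standard deviation of the lognormal
#'   participant responsiveness multiplier (mean fixed at 1); responsiveness
#'   scales each participant's deviation of the scene factor from 1.
#' @param trial_noise_sd log-scale standard deviation of the mean-one
#'   lognormal trial-to-trial gain jitter applied to the whole movie window.
#' @param factor_table optional full override: a data frame with columns
#'   `muscle`, `scene`, `perspective`, `actor_gender`, `attractiveness`,
#'   `participant_gender`, `factor` covering every combination.
#' @return an object of class `femg_modulation`.
#' @export
modulation_spec <- function(baseline_amp = c(CS = 8, OO = 8),
                            cs_scene = c(1.032, 1.064, 1.092, 1.103),
                            oo_scene = c(0.987, 0.985, 0.994, 1.083),
                            cs_attractiveness_shift = 0.0095,
                            cs_actor_gender_scene4_shift = 0.0135,
                            responsiveness_sd = 0.2,
                            trial_noise_sd = 0.05,
                            factor_table = NULL) {
  baseline_amp <- unlist(baseline_amp)
  cs_scene <- unlist(cs_scene)
  oo_scene <- unlist(oo_scene)
  if (length(cs_scene) != 4L || length(oo_scene) != 4L) {
    stopf("scene factor vectors must have length 4")
  }
  if (any(baseline_amp <= 0)) stopf("baseline amplitudes must be positive")
  assert_scalar_number(responsiveness_sd, "responsiveness_sd", lower = 0)
  assert_scalar_number(trial_noise_sd, "trial_noise_sd", lower = 0)

  grid <- expand.grid(scene = 1:4,
                      perspective = c("self", "other"),
                      actor_gender = c("F", "M"),
                      attractiveness = c("high", "low"),
                      participant_gender = c("F", "M"),
                      muscle = c("CS", "OO"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- ifelse(grid$muscle == "CS", cs_scene[grid$scene], oo_scene[grid$scene])
  att <- ifelse(grid$muscle == "CS",
                ifelse(grid$attractiveness == "low", 1, -1) * cs_attractiveness_shift,
                0)
  ag4 <- ifelse(grid$muscle == "CS" & grid$scene == 4L,
                ifelse(grid$actor_gender == "F", 1, -1) * cs_actor_gender_scene4_shift,
                0)
  grid$factor <- base + att + ag4

  if (!is.null(factor_table)) {
    needed <- c("muscle", "scene", "perspective", "actor_gender",
                "attractiveness", "participant_gender", "factor")
    if (!all(needed %in% names(factor_table))) {
      stopf("`factor_table` must have columns: %s", paste(needed, collapse = ", "))
    }
    grid <- merge(grid[setdiff(names(grid), "factor")], factor_table,
                  by = setdiff(needed, "factor"), all.x = TRUE)
    if (anyNA(grid$factor)) stopf("`factor_table` does not cover every cell")
  }
  if (any(grid$factor <= 0)) stopf("all scene factors must be positive")

  structure(list(baseline_amp = baseline_amp,
                 factors = tibble::as_tibble(grid),
                 responsiveness_sd = responsiveness_sd,
                 trial_noise_sd = trial_noise_sd),
            class = "femg_modulation")
}

# Fast lookup array: factor[scene, perspective, actor_gender, attractiveness,
# participant_gender] for one muscle.
factor_array <- function(modulation, muscle) {
  f <- modulation$factors[modulation$factors$muscle == muscle, ]
  arr <- array(NA_real_, dim = c(4, 2, 2, 2, 2),
               dimnames = list(NULL, c("self", "other"), c("F", "M"),
                               c("high", "low"), c("F", "M")))
  arr[cbind(f$scene,
            match(f$perspective, c("self", "other")),
            match(f$actor_gender, c("F", "M")),
            match(f$attractiveness, c("high", "low")),
            match(f$participant_gender, c("F", "M")))] <- f$factor
  arr
}

#' Nuisance (interference and artifact) specification
#'
#' Models what the conditioning chain has to remove: mains interference at
#' 50 Hz and its harmonics, and occasional high-amplitude movement artifacts
#' (frowning, yawning) that contaminate whole trials. Artifacts are transients
#' of 200-800 ms whose amplitude is a multiple of the baseline envelope; they
#' combine a low-frequency (< 20 Hz) sway with an in-band burst so they remain
#' detectable both before and after band filtering.
#'
#' @param mains_amp amplitudes (microvolts) of the 50/100/150 Hz mains
#'   components.
#' @param artifact_prob per-trial probability of an artifact.
#' @param artifact_mult artifact peak amplitude as a multiple of the baseline
#'   envelope amplitude.
#' @param artifact_dur_ms (min, max) artifact duration in ms.
#' @param passband (low, high) edge frequencies in Hz of the band-limited
#'   Gaussian carrier.
#' @return an object of class `femg_nuisance`.
#' @export
nuisance_spec <- function(mains_amp = c(`50` = 10, `100` = 3, `150` = 1),
                          artifact_prob = 0.02,
                          artifact_mult = 10,
                          artifact_dur_ms = c(200, 800),
                          passband = c(30, 400)) {
  mains_amp <- unlist(mains_amp)
  artifact_dur_ms <- unlist(artifact_dur_ms)
  passband <- unlist(passband)
  assert_scalar_number(artifact_prob, "artifact_prob", lower = 0, upper = 1)
  assert_scalar_number(artifact_mult, "artifact_mult", lower = 0)
  if (length(passband) != 2L || passband[1] <= 0 || diff(passband) <= 0) {
    stopf("`passband` must be an increasing positive (low, high) pair")
  }
  if (length(mains_amp) != 3L || any(mains_amp < 0)) {
    stopf("`mains_amp` must be three nonnegative amplitudes (50/100/150 Hz)")
  }
  structure(list(mains_amp = mains_amp,
                 mains_freq = c(50, 100, 150),
                 artifact_prob = artifact_prob,
                 artifact_mult = artifact_mult,
                 artifact_dur_ms = artifact_dur_ms,
                 passband = passband),
            class = "femg_nuisance")
}

#' Synthesize the raw two-channel EMG recording of one participant
#'
#' The signal model is a band-limited Gaussian carrier whose standard
#' deviation is calibrated so that the expected rectified envelope during
#' fixation equals the muscle's baseline amplitude (for zero-mean Gaussian
#' noise `E|x| = sigma * sqrt(2/pi)`). Inside each scene window the carrier is
#' multiplied by the effective scene gain
#' `(1 + responsiveness * (factor - 1)) * trial_jitter`, so scene factors map
#' one-to-one onto baseline-relative envelope ratios in expectation. Mains
#' sinusoids and trial artifacts are then added per [nuisance_spec()].
#' Generation is fully deterministic given the design seed (or an explicit
#' `seed`).
#'
#' @param design a `femg_design` with an event table (see [build_design()]).
#' @param modulation a [modulation_spec()].
#' @param nuisance a [nuisance_spec()].
#' @param participant participant id (e.g. `"P01"`) or index.
#' @param seed optional integer overriding the design-derived substream seed.
#' @param responsiveness optional named vector `c(CS =, OO =)` overriding the
#'   participant responsiveness draw.
#' @param channels channels to generate, in design order. Because channels
#'   are drawn in design order from the participant substream, generating a
#'   leading subset (e.g. only `"CS"`) reproduces exactly the same samples
#'   that channel would have in the full recording.
#' @return an object of class `femg_recording`: a list with `samples` (a
#'   samples x channels matrix, columns CS and OO, in microvolts),
#'   `sampling_rate`, `participant`, `participant_gender`, and the
#'   `responsiveness` used.
#' @export
synthesize_recording <- function(design, modulation, nuisance,
                                 participant, seed = NULL,
                                 responsiveness = NULL,
                                 channels = design$muscles) {
  channels <- design$muscles[design$muscles %in%
                               match.arg(channels, design$muscles,
                                         several.ok = TRUE)]
  stopifnot(inherits(design, "femg_design"),
            inherits(modulation, "femg_modulation"),
            inherits(nuisance, "femg_nuisance"))
  if (is.null(design$events)) {
    stopf("design has no event table; create it with build_design()")
  }
  rate <- design$sampling_rate
  if (rate <= 2 * nuisance$passband[2]) {
    stopf("sampling rate must exceed twice the carrier passband upper edge")
  }
  if (is.numeric(participant)) {
    participant <- sprintf("P%02d", participant)
  }
  ev <- design$events[design$events$participant == participant, ]
  if (nrow(ev) == 0L) stopf("participant '%s' not found in the event table", participant)
  p_index <- match(participant, unique(design$events$participant))
  geom <- epoch_geometry(design)
  bounds <- scene_boundaries(design)
  n_total <- max(ev$onset_sample) + geom$post_onset + rate  # 1 s tail pad

  bp <- signal::butter(4, nuisance$passband / (rate / 2), type = "pass")
  persp_i <- match(ev$perspective, design$perspectives)
  ag_i <- match(ev$actor_gender, design$actor_genders)
  att_i <- match(ev$attractiveness, design$attractiveness_levels)
  pg_i <- match(ev$participant_gender[1], c("F", "M"))
  rsd <- modulation$responsiveness_sd
  tsd <- modulation$trial_noise_sd

  seed <- seed %||% participant_seed(design$seed, p_index, stream = 1L)
  withr::with_seed(seed, {
    resp_drawn <- stats::rlnorm(2, meanlog = -rsd^2 / 2, sdlog = rsd)
    names(resp_drawn) <- design$muscles
    resp <- responsiveness %||% resp_drawn

    samples <- matrix(0, nrow = n_total, ncol = length(channels),
                      dimnames = list(NULL, channels))
    for (muscle in channels) {
      fac <- factor_array(modulation, muscle)
      sigma <- modulation$baseline_amp[[muscle]] * sqrt(pi / 2)
      carrier <- iir_filter(bp$b, bp$a, stats::rnorm(n_total))
      carrier <- carrier * (sigma / stats::sd(carrier))

      gain <- rep(1, n_total)
      mains_phase <- stats::runif(3, 0, 2 * pi)
      artifact <- numeric(0)
      artifact_at <- integer(0)
      for (k in seq_len(nrow(ev))) {
        o <- ev$onset_sample[k]            # 0-based
        tn <- if (tsd > 0) stats::rlnorm(1, -tsd^2 / 2, tsd) else 1
        for (s in 1:4) {
          f <- fac[s, persp_i[k], ag_i[k], att_i[k], pg_i]
          eff <- 1 + resp[[muscle]] * (f - 1)
          if (eff <= 0) stopf("effective scene gain became nonpositive")
          gain[(o + bounds[s] + 1L):(o + bounds[s + 1L])] <- eff * tn
        }
        if (stats::runif(1) < nuisance$artifact_prob) {
          dur <- ms_to_samples(stats::runif(1, nuisance$artifact_dur_ms[1],
                                            nuisance$artifact_dur_ms[2]), rate)
          start <- o + floor(stats::runif(1) * (geom$movie - dur))
          amp <- nuisance$artifact_mult * modulation$baseline_amp[[muscle]]
          tt <- seq_len(dur) / rate
          shape <- sin(pi * seq_len(dur) / (dur + 1))
          pulse <- amp * shape *
            (0.7 * sin(2 * pi * 6 * tt + stats::runif(1, 0, 2 * pi)) +
               0.7 * stats::rnorm(dur))
          artifact <- c(artifact, pulse)
          artifact_at <- c(artifact_at, start + seq_len(dur))
        }
      }
      x <- carrier * gain
      if (any(nuisance$mains_amp > 0)) {
        tt <- (seq_len(n_total) - 1) / rate
        for (h in 1:3) {
          if (nuisance$mains_amp[h] > 0) {
            x <- x + nuisance$mains_amp[h] *
              sin(2 * pi * nuisance$mains_freq[h] * tt + mains_phase[h])
          }
        }
      }
      if (length(artifact_at)) x[artifact_at] <- x[artifact_at] + artifact
      samples[, muscle] <- x
    }
  })

  structure(list(samples = samples,
                 channels = channels,
                 sampling_rate = rate,
                 participant = participant,
                 participant_gender = ev$participant_gender[1],
                 responsiveness = resp,
                 n_samples = n_total),
            class = "femg_recording")
}

#' @export
print.femg_recording <- function(x, ...) {
  cat(sprintf("<femg_recording> %s (%s): %d samples x %d channels @ %g Hz (%.1f s)\n",
              x$participant, x$participant_gender, x$n_samples,
              ncol(x$samples), x$sampling_rate, x$n_samples / x$sampling_rate))
  invisible(x)
}

#' Default pain-intensity (GRS) generative cell means
#'
#' A realistic 0-10 rating pattern: pain expressed by female and by less
#' attractive actors is rated as more intense, with an additional small
#' advantage for the imagine-other perspective.
#'
#' @return a tibble with columns `perspective`, `actor_gender`,
#'   `attractiveness`, `grs_mean` (8 rows).
#' @export
default_grs_cell_means <- function() {
  base <- expand.grid(perspective = c("self", "other"),
                      actor_gender = c("F", "M"),
                      attractiveness = c("high", "low"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cell <- c("F.high" = 4.69, "F.low" = 5.45, "M.high" = 4.24, "M.low" = 4.49)
  base$grs_mean <- cell[paste(base$actor_gender, base$attractiveness, sep = ".")] +
    ifelse(base$perspective == "other", 0.115, -0.115)
  tibble::as_tibble(base)
}

#' Generate per-trial pain-intensity ratings
#'
#' Each rating is its condition cell mean plus Gaussian noise, clamped to the
#' 0-10 graphic rating scale. Deterministic given the design seed (one
#' substream per participant).
#'
#' @param design a `femg_design` with events.
#' @param cell_means data frame with columns `perspective`, `actor_gender`,
#'   `attractiveness` and `grs_mean`; see [default_grs_cell_means()].
#' @param sd rating noise standard deviation (>= 0).
#' @param seed optional integer overriding the design-derived seed.
#' @return tibble with columns `participant`, `trial`, `grs`.
#' @export
generate_ratings <- function(design, cell_means = default_grs_cell_means(),
                             sd = 1, seed = NULL) {
  stopifnot(inherits(design, "femg_design"))
  if (is.null(design$events)) stopf("design has no event table")
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0) {
    stopf("`sd` must be a nonnegative number")
  }
  if (any(cell_means$grs_mean < 0 | cell_means$grs_mean > 10)) {
    stopf("GRS cell means must lie in [0, 10]")
  }
  ev <- dplyr::left_join(design$events, cell_means,
                         by = c("perspective", "actor_gender", "attractiveness"))
  if (anyNA(ev$grs_mean)) stopf("`cell_means` does not cover every condition cell")

  pids <- unique(ev$participant)
  out <- lapply(seq_along(pids), function(i) {
    rows <- ev[ev$participant == pids[i], ]
    s <- if (is.null(seed)) participant_seed(design$seed, i, stream = 2L)
         else participant_seed(seed, i, stream = 2L)
    withr::with_seed(s, {
      score <- rows$grs_mean + stats::rnorm(nrow(rows), 0, sd)
    })
    tibble::tibble(participant = rows$participant, trial = rows$trial,
                   grs = pmin(10, pmax(0, score)))
  })
  dplyr::bind_rows(out)
}

#' Generate trait-empathy (IRI subscale) scores
#'
#' Empathic concern (EC) is drawn so that its correlation with a supplied
#' per-participant muscle-response score targets `coupling_r`; personal
#' distress (PD) and perspective taking (PT) are independent. Scores are
#' rounded to integers and clamped to the admissible subscale range
#' (7 items scored 0-4, i.e. 0-28, by default).
#'
#' @param n number of participants.
#' @param coupling_r target correlation between EC and the response scores
#'   (`|coupling_r| < 1`).
#' @param muscle_response_scores numeric vector of length `n`, e.g. the
#'   per-participant corrugator responsiveness or measured scene-4 response.
#' @param seed integer seed.
#' @param subscale_means,subscale_sds generative means and standard
#'   deviations, named EC/PD/PT.
#' @param score_range admissible (min, max) integer score range.
#' @return tibble with columns `participant_index`, `EC`, `PD`, `PT`.
#' @export
generate_traits <- function(n, coupling_r, muscle_response_scores, seed = 1L,
                            subscale_means = c(EC = 19, PD = 12, PT = 18),
                            subscale_sds = c(EC = 4, PD = 4.5, PT = 4),
                            score_range = c(0, 28)) {
  assert_scalar_number(coupling_r, "coupling_r")
  if (abs(coupling_r) >= 1) stopf("`coupling_r` must satisfy |r| < 1")
  if (length(muscle_response_scores) != n) {
    stopf("`muscle_response_scores` must have length n = %d", n)
  }
  sd_resp <- stats::sd(muscle_response_scores)
  if (coupling_r != 0 && (is.na(sd_resp) || sd_resp == 0)) {
    stopf("response scores have zero variance; coupling is impossible")
  }
  clamp <- function(x) pmin(score_range[2], pmax(score_range[1], round(x)))
  withr::with_seed(seed, {
    z_resp <- if (sd_resp > 0) as.numeric(scale(muscle_response_scores)) else rep(0, n)
    ec_z <- coupling_r * z_resp + sqrt(1 - coupling_r^2) * stats::rnorm(n)
    ec <- clamp(subscale_means[["EC"]] + subscale_sds[["EC"]] * ec_z)
    pd <- clamp(stats::rnorm(n, subscale_means[["PD"]], subscale_sds[["PD"]]))
    pt <- clamp(stats::rnorm(n, subscale_means[["PT"]], subscale_sds[["PT"]]))
  })
  tibble::tibble(participant_index = seq_len(n), EC = ec, PD = pd, PT = pt)
}

#' Simulate condition-table cell means under the global null
#'
#' Draws a balanced participant x condition cell-mean table directly (subject
#' random intercept plus independent cell noise, no condition effects),
#' bypassing signal synthesis. Intended for type-I-error calibration of the
#' mixed repeated-measures ANOVA, where thousands of replicate tables are
#' needed.
#'
#' @param n_participants,n_female design size.
#' @param muscle label stored in the `muscle` column.
#' @param subject_sd standard deviation of the participant random intercept.
#' @param noise_sd standard deviation of the independent cell-level noise.
#' @param seed integer seed.
#' @return a condition table (tibble) as produced by
#'   [build_condition_table()], with `n_trials = 4` in every cell.
#' @export
simulate_null_condition_table <- function(n_participants, n_female,
                                          muscle = "CS",
                                          subject_sd = 0.03, noise_sd = 0.05,
                                          seed = 1L) {
  genders <- rep(c("F", "M"), c(n_female, n_participants - n_female))
  grid <- expand.grid(scene = factor(1:4),
                      attractiveness = c("high", "low"),
                      actor_gender = c("F", "M"),
                      perspective = c("self", "other"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- nrow(grid)
  withr::with_seed(seed, {
    re <- stats::rnorm(n_participants, 0, subject_sd)
    eps <- stats::rnorm(n_participants * m, 0, noise_sd)
  })
  out <- grid[rep(seq_len(m), times = n_participants), ]
  out$participant <- rep(sprintf("P%02d", seq_len(n_participants)), each = m)
  out$participant_gender <- rep(genders, each = m)
  out$muscle <- muscle
  out$mean_rel <- 1 + rep(re, each = m) + eps
  out$n_trials <- 4L
  tibble::as_tibble(out[c("participant", "participant_gender", "muscle",
                          "perspective", "actor_gender", "attractiveness",
                          "scene", "mean_rel", "n_trials")])
}

#' Simulate a complete experiment
#'
#' Convenience wrapper generating recordings for every participant together
#' with ratings and trait scores. For large designs prefer [run_pipeline()],
#' which processes recordings one participant at a time instead of holding
#' them all in memory.
#'
#' @param design a `femg_design` with events.
#' @param modulation,nuisance generative specifications.
#' @param grs_cell_means,grs_sd rating generator settings.
#' @param trait_coupling_r target EC / corrugator-responsiveness correlation.
#' @return list with `design`, `recordings` (named list), `ratings`,
#'   `traits`, and `responsiveness` (participant x muscle tibble).
#' @export
simulate_experiment <- function(design,
                                modulation = modulation_spec(),
                                nuisance = nuisance_spec(),
                                grs_cell_means = default_grs_cell_means(),
                                grs_sd = 1,
                                trait_coupling_r = 0.42) {
  pids <- unique(design$events$participant)
  recordings <- lapply(pids, function(p) {
    synthesize_recording(design, modulation, nuisance, p)
  })
  names(recordings) <- pids
  resp <- tibble::tibble(
    participant = pids,
    CS = vapply(recordings, function(r) r$responsiveness[["CS"]], 0),
    OO = vapply(recordings, function(r) r$responsiveness[["OO"]], 0)
  )
  ratings <- generate_ratings(design, grs_cell_means, grs_sd)
  traits <- generate_traits(length(pids), trait_coupling_r, resp$CS,
                            seed = participant_seed(design$seed, 0L, stream = 3L))
  traits$participant <- pids[traits$participant_index]
  list(design = design, recordings = recordings, ratings = ratings,
       traits = traits, responsiveness = resp)
}
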