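#' Experimental design specification
#'
#' Describes the structure of one empathy-for-pain EMG session: participants
#' watch short movies of actors in painful situations while corrugator
#' supercilii (CS) and orbicularis oculi (OO) EMG is recorded. Each movie is a
#' fixed sequence of four scenes (neutral face, action leading to pain, pain
#' stimulus, painful facial expression) and is shown once under an
#' imagine-self and once under an imagine-other instruction.
#'
#' The trial grid is fully crossed: `situations x actor gender x actor
#' attractiveness x perspective`, i.e. 4 x 2 x 2 x 2 = 32 trials per
#' participant with the default four situations.
#'
#' @param n_participants number of participants.
#' @param n_female number of female participants (the rest are male).
#' @param sampling_rate EMG sampling rate in Hz.
#' @param fixation_range_ms minimum and maximum duration (ms) of the
#'   pre-movie fixation cross; actual durations are drawn uniformly.
#' @param movie_ms movie duration in ms; must equal `sum(scene_ms)`.
#' @param scene_ms ordered durations (ms) of the four movie scenes.
#' @param post_ms post-movie interval retained in each epoch (ms).
#' @param epoch_pre_ms pre-movie interval retained in each epoch (ms).
#' @param baseline_ms length of the baseline window (ms), taken as the
#'   interval immediately preceding movie onset.
#' @param perspectives labels of the two perspective-taking instructions.
#' @param actor_genders labels of the actor-gender factor.
#' @param attractiveness_levels labels of the actor-attractiveness factor.
#' @param situations labels of the four pain-inducing situations.
#' @param seed integer seed controlling all randomisation derived from this
#'   design (trial order, fixation jitter, and the default seeds of the
#'   synthesis functions).
#' @return an object of class `femg_design` (a list).
#' @seealso [build_design()] which also generates the event table.
#' @export
design_spec <- function(n_participants,
                        n_female,
                        sampling_rate = 1024,
                        fixation_range_ms = c(3500, 7500),
                        movie_ms = 5720,
                        scene_ms = c(520, 1960, 240, 3000),
                        post_ms = 500,
                        epoch_pre_ms = 2500,
                        baseline_ms = 2000,
                        perspectives = c("self", "other"),
                        actor_genders = c("F", "M"),
                        attractiveness_levels = c("high", "low"),
                        situations = c("finger_smash", "lip_burn",
                                       "foot_hit", "finger_prick"),
                        seed = 1L) {
  assert_scalar_number(n_participants, "n_participants", lower = 1)
  assert_scalar_number(n_female, "n_female", lower = 0, upper = n_participants)
  assert_scalar_number(sampling_rate, "sampling_rate", lower = 1)
  if (length(scene_ms) != 4L || any(scene_ms <= 0)) {
    stopf("`scene_ms` must be four positive scene durations")
  }
  if (sum(scene_ms) != movie_ms) {
    stopf("scene durations (%s ms) must sum to the movie duration (%s ms)",
          sum(scene_ms), movie_ms)
  }
  if (length(fixation_range_ms) != 2L || diff(fixation_range_ms) < 0) {
    stopf("`fixation_range_ms` must be an increasing (min, max) pair")
  }
  if (!(baseline_ms <= epoch_pre_ms && epoch_pre_ms <= fixation_range_ms[1])) {
    stopf("need baseline_ms <= epoch_pre_ms <= min fixation duration (got %s, %s, %s)",
          baseline_ms, epoch_pre_ms, fixation_range_ms[1])
  }
  if (length(perspectives) != 2L) stopf("exactly two perspectives are supported")

  design <- structure(list(
    n_participants = as.integer(n_participants),
    n_female = as.integer(n_female),
    sampling_rate = sampling_rate,
    fixation_range_ms = fixation_range_ms,
    movie_ms = movie_ms,
    scene_ms = scene_ms,
    post_ms = post_ms,
    epoch_pre_ms = epoch_pre_ms,
    baseline_ms = baseline_ms,
    perspectives = perspectives,
    actor_genders = actor_genders,
    attractiveness_levels = attractiveness_levels,
    situations = situations,
    muscles = c("CS", "OO"),
    seed = as.integer(seed)
  ), class = "femg_design")

  design$trials_per_participant <- length(situations) *
    length(actor_genders) * length(attractiveness_levels) *
    length(perspectives)
  design
}

#' @export
print.femg_design <- function(x, ...) {
  cat("<femg_design>\n")
  cat(sprintf("  participants : %d (%d female)\n", x$n_participants, x$n_female))
  cat(sprintf("  sampling rate: %g Hz\n", x$sampling_rate))
  cat(sprintf("  trials/ppt   : %d (%d situations x %d actors x %d perspectives)\n",
              x$trials_per_participant, length(x$situations),
              length(x$actor_genders) * length(x$attractiveness_levels),
              length(x$perspectives)))
  cat(sprintf("  scenes (ms)  : %s (movie %d ms)\n",
              paste(x$scene_ms, collapse = "/"), x$movie_ms))
  if (!is.null(x$events)) {
    cat(sprintf("  events       : %d rows\n", nrow(x$events)))
  }
  invisible(x)
}

# Scene boundaries relative to movie onset, in samples (0-based, half-open).
# Rounding is applied to the cumulative boundaries, not the durations, so the
# four scene windows always partition the movie window exactly.
scene_boundaries <- function(design) {
  ms_to_samples(cumsum(c(0, design$scene_ms)), design$sampling_rate)
}

# Epoch geometry in samples.
epoch_geometry <- function(design) {
  rate <- design$sampling_rate
  pre <- ms_to_samples(design$epoch_pre_ms, rate)
  total <- ms_to_samples(design$epoch_pre_ms + design$movie_ms + design$post_ms,
                         rate)
  list(pre = pre,
       movie = ms_to_samples(design$movie_ms, rate),
       total = total,
       post_onset = total - pre,
       baseline = ms_to_samples(design$baseline_ms, rate))
}

#' Build a randomized experimental design with its event table
#'
#' Generates the per-participant trial schedule: trials are blocked by
#' perspective, block order is counterbalanced across participants within each
#' gender (half start with imagine-self), clip order is randomized
#' independently within each block, and each movie onset is preceded by a
#' fixation interval drawn uniformly from the design's fixation range.
#' Randomisation uses a deterministic per-participant substream of `seed`, so
#' regenerating with the same arguments is byte-identical and adding
#' participants does not perturb existing ones.
#'
#' @inheritParams design_spec
#' @param ... further arguments passed to [design_spec()].
#' @return a `femg_design` whose `$events` element is a tibble with one row
#'   per trial: `participant`, `participant_gender`, `trial`, `block`,
#'   `perspective`, `actor_gender`, `attractiveness`, `situation`,
#'   `onset_sample` (0-based), `onset_s`, and `excluded`.
#' @export
build_design <- function(n_participants, n_female, seed = 1L, ...) {
  design <- design_spec(n_participants = n_participants, n_female = n_female,
                        seed = seed, ...)
  rate <- design$sampling_rate
  geom <- epoch_geometry(design)

  clips <- expand.grid(situation = design$situations,
                       actor_gender = design$actor_genders,
                       attractiveness = design$attractiveness_levels,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  genders <- rep(c("F", "M"), c(design$n_female,
                                design$n_participants - design$n_female))
  # counterbalance block order within each gender: odd-ranked start self
  rank_in_gender <- stats::ave(seq_len(design$n_participants), genders,
                               FUN = seq_along)

  per_participant <- lapply(seq_len(design$n_participants), function(i) {
    pid <- sprintf("P%02d", i)
    start_self <- rank_in_gender[i] %% 2L == 1L
    block_persp <- if (start_self) design$perspectives else rev(design$perspectives)
    withr::with_seed(participant_seed(design$seed, i, stream = 0L), {
      rows <- do.call(rbind, lapply(1:2, function(b) {
        ord <- sample.int(nrow(clips))
        cbind(clips[ord, , drop = FALSE],
              perspective = block_persp[b], block = b)
      }))
      n_tr <- nrow(rows)
      gaps_ms <- stats::runif(n_tr, design$fixation_range_ms[1],
                              design$fixation_range_ms[2])
      gap_samples <- ms_to_samples(gaps_ms, rate)
      trial_span <- geom$post_onset  # movie + post window
      onsets <- integer(n_tr)
      cursor <- 0L
      for (k in seq_len(n_tr)) {
        onsets[k] <- cursor + gap_samples[k]
        cursor <- onsets[k] + trial_span
      }
      tibble::tibble(
        participant = pid,
        participant_gender = genders[i],
        trial = seq_len(n_tr),
        block = rows$block,
        perspective = rows$perspective,
        actor_gender = rows$actor_gender,
        attractiveness = rows$attractiveness,
        situation = rows$situation,
        onset_sample = onsets,
        onset_s = onsets / rate,
        excluded = FALSE
      )
    })
  })

  design$events <- dplyr::bind_rows(per_participant)
  design
}
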