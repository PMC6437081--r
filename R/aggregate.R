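#' Collapse trial-level scene means into the balanced condition table
#'
#' Averages retained trials within each participant x muscle x perspective x
#' actor gender x attractiveness x scene cell (up to 4 situation trials per
#' cell). Participants missing any cell for a muscle are dropped from that
#' muscle's table only (listwise per muscle), which is what produces
#' different error degrees of freedom across the per-muscle analyses; the
#' roster of drops is attached as an attribute and messaged.
#'
#' @param trial_scene trial-scene tibble from [preprocess_recording()].
#' @param events the event table (trial attributes).
#' @param quiet suppress the drop-roster message.
#' @return tibble with columns `participant`, `participant_gender`,
#'   `muscle`, `perspective`, `actor_gender`, `attractiveness`, `scene`
#'   (factor), `mean_rel`, `n_trials`; attribute `dropped` lists per-muscle
#'   participant drops.
#' @export
build_condition_table <- function(trial_scene, events, quiet = FALSE) {
  key <- c("participant", "trial", "muscle", "scene")
  if (anyDuplicated(trial_scene[key])) {
    stopf("duplicate (participant, trial, muscle, scene) rows in trial_scene")
  }
  joined <- dplyr::inner_join(
    trial_scene[!trial_scene$excluded, ],
    events[c("participant", "participant_gender", "trial", "perspective",
             "actor_gender", "attractiveness")],
    by = c("participant", "trial"))

  cells <- joined |>
    dplyr::group_by(.data$participant, .data$participant_gender, .data$muscle,
                    .data$perspective, .data$actor_gender,
                    .data$attractiveness, .data$scene) |>
    dplyr::summarise(mean_rel = mean(.data$rel_amplitude),
                     n_trials = dplyr::n(), .groups = "drop")

  n_cells_expected <- 2L * 2L * 2L * 4L
  completeness <- cells |>
    dplyr::count(.data$muscle, .data$participant, name = "n_cells")
  dropped <- completeness[completeness$n_cells < n_cells_expected, ]
  if (nrow(dropped) > 0L) {
    if (!quiet) {
      message(sprintf("dropping %d participant-muscle combination(s) with empty cells: %s",
                      nrow(dropped),
                      paste(dropped$participant, dropped$muscle,
                            sep = "/", collapse = ", ")))
    }
    cells <- dplyr::anti_join(cells, dropped[c("muscle", "participant")],
                              by = c("muscle", "participant"))
  }
  cells$scene <- factor(cells$scene, levels = 1:4)
  attr(cells, "dropped") <- dropped
  cells
}

#' Collapse trial ratings into the per-condition GRS table
#'
#' Pain-intensity ratings are averaged over the situation trials of each
#' participant x perspective x actor gender x attractiveness cell (scene is
#' not a factor for ratings: one rating is given per movie).
#'
#' @param ratings tibble with `participant`, `trial`, `grs`.
#' @param events the event table.
#' @return tibble with 8 cells per participant: `participant`,
#'   `participant_gender`, `perspective`, `actor_gender`, `attractiveness`,
#'   `grs`, `n_trials`.
#' @export
build_grs_table <- function(ratings, events) {
  joined <- dplyr::inner_join(
    events[c("participant", "participant_gender", "trial", "perspective",
             "actor_gender", "attractiveness")],
    ratings, by = c("participant", "trial"))
  out <- joined |>
    dplyr::group_by(.data$participant, .data$participant_gender,
                    .data$perspective, .data$actor_gender,
                    .data$attractiveness) |>
    dplyr::summarise(n_trials = sum(!is.na(.data$grs)),
                     grs = mean(.data$grs, na.rm = TRUE), .groups = "drop")
  if (any(out$n_trials < 2L)) {
    warnf("%d GRS cell(s) are based on fewer than 2 ratings",
          sum(out$n_trials < 2L))
  }
  out
}
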