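#' Cut a filtered recording into event-related epochs
#'
#' Each retained trial yields one epoch per muscle covering the pre-movie
#' fixation interval, the movie, and the post-movie interval (8720 ms at the
#' default design, i.e. `round(8.72 * rate)` samples). Sample windows are
#' half-open `[start, end)` with 0-based onsets, so an onset at sample 10240
#' at 1024 Hz gives the window `[7680, 16609)`. Trials whose epoch would
#' extend past either edge of the recording are excluded with a logged
#' reason, not an error.
#'
#' @param recording a (typically band-filtered) `femg_recording`.
#' @param events event rows for this participant (defaults to the rows of
#'   `design$events` matching the recording's participant).
#' @param design the `femg_design`.
#' @return an object of class `femg_epochs`: a list with one trials x samples
#'   matrix per muscle, the event table with an `edge_excluded` flag, the
#'   1-based `onset_index` of movie onset within the epoch, and geometry.
#' @export
cut_epochs <- function(recording, events = NULL, design) {
  stopifnot(inherits(recording, "femg_recording"), inherits(design, "femg_design"))
  if (is.null(events)) {
    events <- design$events[design$events$participant == recording$participant, ]
  }
  geom <- epoch_geometry(design)
  n <- recording$n_samples
  start <- events$onset_sample - geom$pre          # 0-based epoch start
  ok <- start >= 0L & (start + geom$total) <= n
  events$edge_excluded <- !ok

  idx_rows <- which(ok)
  mats <- lapply(seq_along(recording$channels), function(m) {
    out <- matrix(NA_real_, nrow = nrow(events), ncol = geom$total)
    for (k in idx_rows) {
      out[k, ] <- recording$samples[(start[k] + 1L):(start[k] + geom$total), m]
    }
    out
  })
  names(mats) <- recording$channels

  structure(list(epochs = mats,
                 events = events,
                 onset_index = geom$pre + 1L,   # 1-based within epoch
                 n_samples = geom$total,
                 sampling_rate = recording$sampling_rate,
                 participant = recording$participant),
            class = "femg_epochs")
}

#' Flag trials contaminated by high-amplitude artifacts
#'
#' Automated replacement for visual trial screening: a trial is flagged for a
#' muscle when any sample of its epoch window in the filtered signal exceeds
#' `k` times a robust scale estimate (`1.4826 * MAD`, computed over the whole
#' recording of that participant and muscle, hence insensitive to the
#' artifacts themselves). Flags propagate to all scene rows of that trial.
#'
#' @param recording a band-filtered `femg_recording`.
#' @param events event rows for this participant (default: from `design`).
#' @param design the `femg_design`.
#' @param k threshold multiplier (default 8); `k = Inf` disables flagging.
#' @return tibble with columns `participant`, `trial`, `muscle`, `artifact`.
#' @export
detect_artifacts <- function(recording, events = NULL, design, k = 8) {
  stopifnot(inherits(recording, "femg_recording"))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    stopf("`k` must be a positive number")
  }
  if (is.null(events)) {
    events <- design$events[design$events$participant == recording$participant, ]
  }
  geom <- epoch_geometry(design)
  start <- pmax(0L, events$onset_sample - geom$pre)
  end <- pmin(recording$n_samples, events$onset_sample - geom$pre + geom$total)

  out <- lapply(seq_along(recording$channels), function(m) {
    x <- recording$samples[, m]
    thr <- k * stats::mad(x)
    flagged <- vapply(seq_len(nrow(events)), function(j) {
      if (end[j] <= start[j]) return(FALSE)
      any(abs(x[(start[j] + 1L):end[j]]) > thr)
    }, logical(1))
    tibble::tibble(participant = events$participant,
                   trial = events$trial,
                   muscle = recording$channels[m],
                   artifact = flagged)
  })
  dplyr::bind_rows(out)
}

#' Baseline-normalize an envelope epoch
#'
#' The baseline is the mean envelope over the window immediately preceding
#' movie onset (2000 ms by default); every sample of the epoch is divided by
#' this scalar, so 1.0 means "at baseline". Degenerate baselines (below
#' `eps`) mark the trial as excluded rather than producing infinities.
#'
#' @param envelope numeric envelope epoch.
#' @param design the `femg_design`.
#' @param onset_index 1-based index of movie onset within the epoch
#'   (default: the design's epoch geometry).
#' @param eps smallest admissible baseline (microvolts).
#' @return list with `normalized` (numeric vector, `NA` if excluded),
#'   `baseline`, and `excluded`.
#' @export
baseline_and_normalize <- function(envelope, design, onset_index = NULL,
                                   eps = 1e-6) {
  geom <- epoch_geometry(design)
  onset_index <- onset_index %||% (geom$pre + 1L)
  if (onset_index - geom$baseline < 1L) {
    stopf("epoch does not contain the full baseline window")
  }
  baseline <- mean(envelope[(onset_index - geom$baseline):(onset_index - 1L)])
  if (!is.finite(baseline) || baseline < eps) {
    return(list(normalized = rep(NA_real_, length(envelope)),
                baseline = baseline, excluded = TRUE))
  }
  list(normalized = envelope / baseline, baseline = baseline, excluded = FALSE)
}

#' Mean baseline-relative amplitude per movie scene
#'
#' Averages a normalized envelope epoch over each of the four scene windows.
#' Scene boundaries are obtained by rounding the cumulative scene durations
#' onto the sample grid, so the windows partition the movie interval exactly
#' (no gaps or overlaps).
#'
#' @param normalized numeric normalized envelope epoch.
#' @param design the `femg_design`.
#' @param onset_index 1-based movie-onset index within the epoch.
#' @return named numeric vector of four scene means.
#' @export
scene_means <- function(normalized, design, onset_index = NULL) {
  geom <- epoch_geometry(design)
  onset_index <- onset_index %||% (geom$pre + 1L)
  bounds <- scene_boundaries(design)
  if (any(diff(bounds) <= 0)) {
    stopf("scene boundary rounding produced a zero-length scene window")
  }
  if (onset_index - 1L + bounds[5] > length(normalized)) {
    stopf("epoch does not contain the full movie window")
  }
  vapply(1:4, function(s) {
    mean(normalized[(onset_index + bounds[s]):(onset_index + bounds[s + 1L] - 1L)])
  }, numeric(1)) |> stats::setNames(paste0("scene", 1:4))
}

#' Run the full conditioning chain on one participant's recording
#'
#' Filter the continuous signal, flag artifact trials, cut epochs, extract
#' the rectified envelope per epoch, divide by the pre-movie baseline, and
#' average within each scene window. This is the per-participant unit of work
#' of the pipeline.
#'
#' @param recording a raw `femg_recording`.
#' @param design the `femg_design`.
#' @param events event rows (default from `design`).
#' @param spec a [filter_spec()].
#' @param artifact_k MAD-threshold multiplier for [detect_artifacts()].
#' @param channels channels to process (default: all in the recording).
#' @return a trial-scene tibble with one row per trial x muscle x scene:
#'   `participant`, `trial`, `muscle`, `scene`, `rel_amplitude`, `baseline`,
#'   `excluded`, `reason`.
#' @export
preprocess_recording <- function(recording, design, events = NULL,
                                 spec = filter_spec(), artifact_k = 8,
                                 channels = recording$channels) {
  if (is.null(events)) {
    events <- design$events[design$events$participant == recording$participant, ]
  }
  channels <- intersect(recording$channels, channels)
  if (length(channels) == 0L) stopf("no requested channel is present in the recording")
  if (!identical(channels, recording$channels)) {
    recording$samples <- recording$samples[, channels, drop = FALSE]
    recording$channels <- channels
  }
  filtered <- apply_filter_chain(recording, spec)
  flags <- detect_artifacts(filtered, events, design, k = artifact_k)
  ep <- cut_epochs(filtered, events, design)
  geom <- epoch_geometry(design)

  n_tr <- nrow(events)
  rows <- lapply(recording$channels, function(muscle) {
    art <- flags$artifact[flags$muscle == muscle]
    rel <- matrix(NA_real_, n_tr, 4)
    baseline <- rep(NA_real_, n_tr)
    reason <- rep(NA_character_, n_tr)
    for (k in seq_len(n_tr)) {
      if (ep$events$edge_excluded[k]) {
        reason[k] <- "edge"
        next
      }
      if (art[k]) {
        reason[k] <- "artifact"
        next
      }
      env <- extract_envelope(ep$epochs[[muscle]][k, ], spec,
                              sampling_rate = recording$sampling_rate)
      bl <- baseline_and_normalize(env, design, onset_index = ep$onset_index)
      baseline[k] <- bl$baseline
      if (bl$excluded) {
        reason[k] <- "degenerate_baseline"
        next
      }
      rel[k, ] <- scene_means(bl$normalized, design, onset_index = ep$onset_index)
    }
    tibble::tibble(
      participant = rep(events$participant, each = 4L),
      trial = rep(events$trial, each = 4L),
      muscle = muscle,
      scene = rep(1:4, n_tr),
      rel_amplitude = as.vector(t(rel)),
      baseline = rep(baseline, each = 4L),
      excluded = rep(!is.na(reason), each = 4L),
      reason = rep(reason, each = 4L))
  })
  dplyr::bind_rows(rows)
}
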