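# constructed trial-scene tables: fast, no signal processing involved

make_trial_scene <- function(design, value = 1) {
  ev <- design$events
  grid <- expand.grid(row = seq_len(nrow(ev)), muscle = c("CS", "OO"),
                      scene = 1:4, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  tibble::tibble(participant = ev$participant[grid$row],
                 trial = ev$trial[grid$row],
                 muscle = grid$muscle, scene = grid$scene,
                 rel_amplitude = value, baseline = 8,
                 excluded = FALSE, reason = NA_character_)
}

test_that("condition cells average the situation trials", {
  design <- build_design(3, 2, seed = 41)
  ts <- make_trial_scene(design)
  withr::with_seed(1, ts$rel_amplitude <- rlnorm(nrow(ts), 0, 0.1))
  ct <- build_condition_table(ts, design$events)
  expect_equal(nrow(ct), 3L * 2L * 32L)
  expect_true(all(ct$n_trials == 4L))
  # grand mean identity vs the trial-weighted mean (no drops, equal n)
  expect_equal(mean(ct$mean_rel), mean(ts$rel_amplitude), tolerance = 1e-12)
})

test_that("partial exclusions shrink cells; full-cell loss drops per muscle", {
  design <- build_design(3, 2, seed = 42)
  ts <- make_trial_scene(design)
  ev1 <- design$events[design$events$participant == "P01", ]
  cell_trials <- ev1$trial[ev1$perspective == "self" &
                             ev1$actor_gender == "F" &
                             ev1$attractiveness == "high"]
  expect_length(cell_trials, 4L)

  # one missing trial: cell mean over 3, participant retained
  ts1 <- ts
  ts1$excluded[ts1$participant == "P01" & ts1$muscle == "CS" &
                 ts1$trial == cell_trials[1]] <- TRUE
  ct1 <- build_condition_table(ts1, design$events, quiet = TRUE)
  cell <- ct1[ct1$participant == "P01" & ct1$muscle == "CS" &
                ct1$perspective == "self" & ct1$actor_gender == "F" &
                ct1$attractiveness == "high", ]
  expect_true(all(cell$n_trials == 3L))
  expect_true("P01" %in% ct1$participant[ct1$muscle == "CS"])

  # whole cell gone: P01 dropped for CS only, OO untouched
  ts2 <- ts
  ts2$excluded[ts2$participant == "P01" & ts2$muscle == "CS" &
                 ts2$trial %in% cell_trials] <- TRUE
  expect_message(ct2 <- build_condition_table(ts2, design$events), "dropping")
  expect_false("P01" %in% ct2$participant[ct2$muscle == "CS"])
  expect_true("P01" %in% ct2$participant[ct2$muscle == "OO"])
  dropped <- attr(ct2, "dropped")
  expect_identical(dropped$participant, "P01")
  expect_identical(dropped$muscle, "CS")

  # other participants' cells are untouched by the drop
  ct0 <- build_condition_table(ts, design$events, quiet = TRUE)
  others0 <- ct0[ct0$participant != "P01", ]
  others2 <- ct2[ct2$participant != "P01", ]
  expect_equal(others2$mean_rel, others0$mean_rel)
})

test_that("duplicate trial-scene rows are a data-integrity error", {
  design <- build_design(2, 1, seed = 43)
  ts <- make_trial_scene(design)
  expect_error(build_condition_table(rbind(ts, ts[1, ]), design$events),
               "duplicate")
})

test_that("GRS cell means follow the generator exactly when noise-free", {
  design <- build_design(4, 2, seed = 44)
  exact <- generate_ratings(design, sd = 0)
  tab <- build_grs_table(exact, design$events)
  expect_equal(nrow(tab), 4L * 8L)
  expect_true(all(tab$n_trials == 4L))
  ref <- dplyr::inner_join(tab, default_grs_cell_means(),
                           by = c("perspective", "actor_gender", "attractiveness"))
  expect_equal(ref$grs, ref$grs_mean)

  const <- exact
  const$grs <- 5
  tab5 <- build_grs_table(const, design$events)
  expect_true(all(tab5$grs == 5))
})
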