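rate <- 1024

# a design whose event table we overwrite with hand-placed onsets
toy_design <- function(onsets) {
  design <- build_design(1, 1, seed = 1)
  ev <- design$events[seq_along(onsets), ]
  ev$trial <- seq_along(onsets)
  ev$onset_sample <- as.integer(onsets)
  ev$onset_s <- onsets / rate
  design$events <- ev
  design
}

toy_recording <- function(n, values = seq_len(n) - 1) {
  samples <- cbind(CS = values, OO = rep(0, n))
  structure(list(samples = samples, channels = c("CS", "OO"),
                 sampling_rate = rate, participant = "P01",
                 participant_gender = "F", responsiveness = NULL,
                 n_samples = n),
            class = "femg_recording")
}

test_that("millisecond-to-sample conversion and scene partition follow the rounding rule", {
  expect_identical(ms_to_samples(520, rate), 532L)            # 532.48 rounds down
  expect_identical(ms_to_samples(2500, rate), 2560L)
  design <- build_design(1, 1, seed = 1)
  bounds <- facemg:::scene_boundaries(design)
  expect_identical(bounds, c(0L, 532L, 2540L, 2785L, 5857L))
  expect_identical(sum(diff(bounds)), ms_to_samples(5720, rate))  # exact partition
  geom <- facemg:::epoch_geometry(design)
  expect_identical(geom$total, 8929L)                          # round(8.72 * 1024)
  expect_identical(geom$pre, 2560L)
})

test_that("epochs cover the documented half-open sample window", {
  design <- toy_design(10240)
  rec <- toy_recording(20000)
  ep <- cut_epochs(rec, design = design)
  expect_identical(dim(ep$epochs$CS), c(1L, 8929L))
  # 0-based window [7680, 16609): sample values equal their 0-based index
  expect_equal(ep$epochs$CS[1, 1], 7680)
  expect_equal(ep$epochs$CS[1, 8929], 16608)
  expect_identical(ep$onset_index, 2561L)
})

test_that("onsets too close to a recording edge are excluded, not fatal", {
  design <- toy_design(c(100, 10240, 19000))
  rec <- toy_recording(20000)
  ep <- cut_epochs(rec, design = design)
  expect_identical(ep$events$edge_excluded, c(TRUE, FALSE, TRUE))
  expect_true(all(is.na(ep$epochs$CS[1, ])))
})

test_that("epoching identical recordings gives identical epochs", {
  design <- toy_design(c(8000, 22000))
  withr::with_seed(5, v <- rnorm(40000))
  ep1 <- cut_epochs(toy_recording(40000, v), design = design)
  ep2 <- cut_epochs(toy_recording(40000, v), design = design)
  expect_identical(ep1$epochs, ep2$epochs)
})

test_that("baseline normalisation follows the arithmetic contract", {
  design <- build_design(1, 1, seed = 1)
  geom <- facemg:::epoch_geometry(design)
  env <- rep(2, geom$total)
  env[geom$pre + seq_len(geom$post_onset)] <- 3
  out <- baseline_and_normalize(env, design)
  expect_equal(out$baseline, 2)
  expect_equal(out$normalized[geom$pre + 10], 1.5)
  expect_false(out$excluded)

  const <- baseline_and_normalize(rep(5, geom$total), design)
  expect_true(all(const$normalized == 1))

  degenerate <- baseline_and_normalize(rep(0, geom$total), design)
  expect_true(degenerate$excluded)
  expect_true(all(is.na(degenerate$normalized)))
})

test_that("scene means average the movie window exactly", {
  design <- build_design(1, 1, seed = 1)
  geom <- facemg:::epoch_geometry(design)
  bounds <- facemg:::scene_boundaries(design)
  norm <- rep(1, geom$total)
  expect_equal(unname(scene_means(norm, design)), rep(1, 4))
  # step profile: 1.0 in scenes 1-3, 1.2 in scene 4
  norm[(geom$pre + bounds[4] + 1):(geom$pre + bounds[5])] <- 1.2
  expect_equal(unname(scene_means(norm, design)), c(1, 1, 1, 1.2))
})
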