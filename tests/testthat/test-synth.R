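test_that("recording synthesis is seed-deterministic", {
  design <- build_design(2, 1, seed = 31)
  mod <- modulation_spec()
  nui <- nuisance_spec()
  a <- synthesize_recording(design, mod, nui, "P01")
  b <- synthesize_recording(design, mod, nui, "P01")
  expect_identical(a$samples, b$samples)
  c <- synthesize_recording(design, mod, nui, "P02")
  expect_false(identical(a$samples[1:1000, 1], c$samples[1:1000, 1]))
})

test_that("identity modulation passes through the pipeline near 1", {
  design <- build_design(4, 2, seed = 32)   # 128 trials
  ts <- run_participants(design, identity_modulation(), clean_nuisance(),
                         channels = "CS")
  kept <- ts[!ts$excluded, ]
  expect_gt(nrow(kept) / 4, 100)
  expect_lt(abs(mean(kept$rel_amplitude) - 1), 0.02)
})

test_that("an isolated scene-4 factor of 1.2 is recovered within 0.02", {
  design <- build_design(4, 2, seed = 33)
  mod <- modulation_spec(cs_scene = c(1, 1, 1, 1.2), oo_scene = rep(1, 4),
                         cs_attractiveness_shift = 0,
                         cs_actor_gender_scene4_shift = 0,
                         responsiveness_sd = 0, trial_noise_sd = 0)
  ts <- run_participants(design, mod, clean_nuisance(), channels = "CS")
  kept <- ts[!ts$excluded, ]
  means <- tapply(kept$rel_amplitude, kept$scene, mean)
  expect_lt(abs(means[["4"]] - 1.2), 0.02)
  expect_true(all(abs(means[c("1", "2", "3")] - 1) < 0.02))
})

test_that("scene factors act linearly on the recovered envelope", {
  # doubling the scene-4 deviation-free gain doubles the recovered
  # baseline-relative mean
  run_at <- function(f, seed) {
    design <- build_design(7, 4, seed = seed)  # 224 trials per config
    mod <- modulation_spec(cs_scene = c(1, 1, 1, f), oo_scene = rep(1, 4),
                           cs_attractiveness_shift = 0,
                           cs_actor_gender_scene4_shift = 0,
                           responsiveness_sd = 0, trial_noise_sd = 0)
    ts <- run_participants(design, mod, clean_nuisance(), channels = "CS")
    kept <- ts[!ts$excluded & ts$scene == 4, ]
    mean(kept$rel_amplitude)
  }
  m1 <- run_at(0.7, seed = 34)
  m2 <- run_at(1.4, seed = 34)
  expect_lt(abs(m2 / m1 - 2), 0.05 * 2)
})

test_that("nonpositive scene factors are rejected", {
  expect_error(modulation_spec(cs_scene = c(1, 1, 1, -0.2)), "positive")
  expect_error(modulation_spec(cs_scene = c(1, 1, 1, 1),
                               cs_attractiveness_shift = 2), "positive")
})

test_that("ratings follow their generative cell means", {
  design <- build_design(51, 27, seed = 35)
  exact <- generate_ratings(design, sd = 0)
  joined <- dplyr::inner_join(exact, design$events, by = c("participant", "trial"))
  cells <- dplyr::inner_join(joined, default_grs_cell_means(),
                             by = c("perspective", "actor_gender", "attractiveness"))
  expect_equal(cells$grs, cells$grs_mean)

  noisy <- generate_ratings(design, sd = 1)
  expect_true(all(noisy$grs >= 0 & noisy$grs <= 10))
  grs_tab <- build_grs_table(noisy, design$events)
  cellmeans <- dplyr::summarise(
    dplyr::group_by(dplyr::inner_join(grs_tab, default_grs_cell_means(),
                                      by = c("perspective", "actor_gender",
                                             "attractiveness")),
                    perspective, actor_gender, attractiveness),
    err = mean(grs) - grs_mean[1], .groups = "drop")
  expect_true(all(abs(cellmeans$err) < 0.3))
})

test_that("rating generator rejects invalid specifications", {
  design <- build_design(2, 1, seed = 36)
  bad_means <- default_grs_cell_means()
  bad_means$grs_mean[1] <- 11
  expect_error(generate_ratings(design, bad_means), "0, 10")
  expect_error(generate_ratings(design, sd = -1), "nonnegative")
})

test_that("trait coupling targets the requested correlation", {
  withr::with_seed(100, scores <- rlnorm(48, 0, 0.2))
  # null coupling: |r| < 0.3 in at least 95% of replicate draws
  rs <- vapply(1:300, function(s) {
    tr <- generate_traits(48, 0, scores, seed = s)
    cor(tr$EC, scores)
  }, numeric(1))
  expect_gte(mean(abs(rs) < 0.3), 0.95)
  # embedded coupling: recovered r inside the Fisher-z 95% band
  rs42 <- vapply(1:100, function(s) {
    tr <- generate_traits(48, 0.42, scores, seed = s)
    cor(tr$EC, scores)
  }, numeric(1))
  expect_gte(mean(rs42 > 0.12 & rs42 < 0.65), 0.9)
})

test_that("trait generator guards its preconditions", {
  expect_error(generate_traits(10, 1.2, rnorm(10)), "< 1")
  expect_error(generate_traits(10, 0.4, rnorm(9)), "length")
  expect_error(generate_traits(10, 0.4, rep(1, 10)), "zero variance")
  tr <- generate_traits(40, 0.4, rnorm(40), seed = 2)
  expect_true(all(tr$EC >= 0 & tr$EC <= 28))
  expect_true(all(tr$PD >= 0 & tr$PD <= 28))
})
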