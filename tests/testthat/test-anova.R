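test_that("mixed ANOVA reproduces the general-linear-model oracle", {
  for (seed in c(101, 102, 103, 104, 105)) {
    tab <- simulate_null_condition_table(6, 3, seed = seed)
    mine <- mixed_rm_anova(tab, dv = "mean_rel",
                           within = c("perspective", "actor_gender",
                                      "attractiveness", "scene"),
                           between = "participant_gender")
    ref <- aov_oracle_f(tab)
    mine$key <- vapply(mine$effect, normalize_effect_key, "")
    merged <- merge(mine, ref, by = "key")
    expect_equal(nrow(merged), 31L)
    expect_lt(max(abs(merged$f.x - merged$f.y) / merged$f.y), 1e-8)
  }
})

test_that("a two-level within factor reduces to the squared paired t", {
  withr::with_seed(7, x <- matrix(rnorm(24), 12))
  d <- data.frame(participant = rep(sprintf("S%02d", 1:12), 2),
                  cond = rep(c("a", "b"), each = 12), y = c(x))
  a <- mixed_rm_anova(d, dv = "y", within = "cond")
  tt <- t.test(x[, 1], x[, 2], paired = TRUE)
  expect_equal(a$f, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_identical(c(a$df1, a$df2), c(1L, 11L))
  expect_equal(a$p, tt$p.value, tolerance = 1e-12)
})

test_that("sums of squares decompose the total exactly", {
  tab <- simulate_null_condition_table(8, 4, seed = 9)
  a <- mixed_rm_anova(tab, dv = "mean_rel",
                      within = c("perspective", "actor_gender",
                                 "attractiveness", "scene"),
                      between = "participant_gender")
  total <- sum((tab$mean_rel - mean(tab$mean_rel))^2)
  err <- unique(a[c("error_term", "error_ss")])
  expect_equal(sum(a$ss) + sum(err$error_ss), total, tolerance = 1e-8 * total)
  expect_true(all(a$ss >= 0))
})

test_that("partial eta squared is consistent with its own F and dfs", {
  tab <- simulate_null_condition_table(10, 5, seed = 10)
  a <- mixed_rm_anova(tab, dv = "mean_rel",
                      within = c("perspective", "scene"),
                      between = "participant_gender")
  expect_equal(a$pes, partial_eta_squared(a$f, a$df1, a$df2), tolerance = 1e-9)
  expect_error(partial_eta_squared(1, 0, 10), ">= 1")
  expect_error(partial_eta_squared(-1, 1, 10), "nonnegative")
  expect_equal(partial_eta_squared(0, 1, 10), 0)
})

test_that("error degrees of freedom match the study design sizes", {
  # 51 participants, between gender: every within effect tested on df2
  # a multiple of n - 2 = 49
  tab <- simulate_null_condition_table(51, 27, seed = 11)
  a <- mixed_rm_anova(tab, dv = "mean_rel",
                      within = c("perspective", "actor_gender",
                                 "attractiveness"),
                      between = "participant_gender")
  expect_true(all(a$df2 == 49L * a$df1 |
                    (a$effect == "participant_gender" & a$df2 == 49L)))
  scene_a <- mixed_rm_anova(tab, dv = "mean_rel",
                            within = c("perspective", "actor_gender",
                                       "attractiveness", "scene"),
                            between = "participant_gender")
  expect_identical(scene_a$df2[scene_a$effect == "scene"], 147L)  # 3 * 49
})

test_that("degenerate ANOVA inputs raise informative errors", {
  tab <- simulate_null_condition_table(6, 3, seed = 12)
  expect_error(mixed_rm_anova(tab[-1, ], dv = "mean_rel",
                              within = c("perspective", "scene"),
                              between = "participant_gender"),
               "balanced")
  solo <- simulate_null_condition_table(3, 1, seed = 13)
  expect_error(mixed_rm_anova(solo, dv = "mean_rel",
                              within = "scene", between = "participant_gender"),
               "at least 2 subjects")
  flat <- tab
  flat$mean_rel <- 1
  expect_error(mixed_rm_anova(flat, dv = "mean_rel", within = "scene"),
               "error variance")
})

test_that("Greenhouse-Geisser correction is available and bounded", {
  tab <- simulate_null_condition_table(12, 6, seed = 14)
  # build in a clear scene effect so the corrected p is comparable
  tab$mean_rel[tab$scene == "4"] <- tab$mean_rel[tab$scene == "4"] + 0.1
  a <- mixed_rm_anova(tab, dv = "mean_rel", within = c("scene", "perspective"),
                      between = "participant_gender",
                      sphericity = "greenhouse-geisser")
  sc <- a[a$effect == "scene", ]
  expect_true(sc$gg_epsilon >= 1 / 3 && sc$gg_epsilon <= 1)
  # for a clearly significant effect the correction is conservative
  expect_gt(sc$f, 10)
  expect_gte(sc$p_gg, sc$p)
  within_rows <- a[a$error_term != "subjects", ]
  expect_true(all(within_rows$p_gg > 0 & within_rows$p_gg <= 1))
  # two-level factors are sphericity-trivial
  expect_equal(a$gg_epsilon[a$effect == "perspective"], 1)
})
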