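rate <- 1024

test_that("notch comb attenuates 50 Hz mains by at least 40 dB at steady state", {
  # the 0.2 Hz-wide notch has a settling time of several seconds, so use a
  # long sine and measure the interior
  t <- (0:(40 * rate - 1)) / rate
  x <- sin(2 * pi * 50 * t)
  y <- apply_filter_chain(x, filter_spec(), sampling_rate = rate)
  interior <- y[(15 * rate):(30 * rate)]
  expect_lt(sqrt(mean(interior^2)), 0.01)
})

test_that("high-pass removes a DC offset", {
  x <- rep(100, 20 * rate)
  y <- apply_filter_chain(x, filter_spec(), sampling_rate = rate)
  expect_lt(abs(mean(y)), 0.1)
})

test_that("passband gain at 200 Hz is within 5% of unity", {
  t <- (0:(10 * rate - 1)) / rate
  x <- sin(2 * pi * 200 * t)
  y <- apply_filter_chain(x, filter_spec(), sampling_rate = rate)
  interior <- y[(2 * rate):(8 * rate)]
  gain <- sqrt(mean(interior^2)) / sqrt(0.5)
  expect_lt(abs(gain - 1), 0.05)
})

test_that("invalid inputs are rejected with guidance", {
  expect_error(apply_filter_chain(c(1, NA, 3), filter_spec(), sampling_rate = rate),
               "NA/NaN")
  expect_error(apply_filter_chain(rnorm(100), filter_spec(low_pass = 400),
                                  sampling_rate = 700),
               "lower the cutoff")
  expect_error(apply_filter_chain(rnorm(100), filter_spec()), "sampling_rate")
  expect_error(filter_spec(high_pass = 500, low_pass = 400), "below")
  expect_error(filter_spec(notch_bands = list(c(49, 51), c(50, 52))), "disjoint")
})

test_that("filter cascade order is immaterial up to numerics", {
  withr::with_seed(4, x <- rnorm(30 * rate))
  spec <- filter_spec()
  nyq <- rate / 2
  hp <- signal::butter(spec$order, spec$high_pass / nyq, "high")
  notches <- lapply(spec$notch_bands, function(b) {
    signal::butter(spec$notch_order, b / nyq, "stop")
  })
  zp <- function(x, f) facemg:::zero_phase_filter(f$b, f$a, x, pad = rate)
  y1 <- zp(x, hp)
  for (f in notches) y1 <- zp(y1, f)
  y2 <- x
  for (f in notches) y2 <- zp(y2, f)
  y2 <- zp(y2, hp)
  interior <- (5 * rate):(25 * rate)  # exclude edge transients of the notches
  expect_lt(sqrt(mean((y1 - y2)[interior]^2)) / sqrt(mean(y1[interior]^2)),
            0.001)
})

test_that("compiled IIR pass matches the reference implementation", {
  withr::with_seed(9, x <- rnorm(5000))
  f <- signal::butter(4, 0.3, "low")
  mine <- facemg:::iir_filter(f$b, f$a, x)
  ref <- as.numeric(signal::filter(f, x))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("synthetic carrier concentrates its power in the passband", {
  design <- build_design(1, 1, seed = 5)
  rec <- synthesize_recording(design, identity_modulation(), clean_nuisance(),
                              "P01", channels = "CS")
  frac <- band_power_fraction(rec$samples[, "CS"], rate, 30, 400)
  expect_gt(frac, 0.95)
})

test_that("mains interference is suppressed to below 1% residual power", {
  design <- build_design(1, 1, seed = 6)
  nui <- nuisance_spec(mains_amp = c(`50` = 10, `100` = 0, `150` = 0),
                       artifact_prob = 0)
  rec <- synthesize_recording(design, identity_modulation(), nui,
                              "P01", channels = "CS")
  x <- rec$samples[, "CS"]
  y <- apply_filter_chain(x, filter_spec(), sampling_rate = rate)
  p_in <- band_power_fraction(x, rate, 49.75, 50.25) * sum((x - mean(x))^2)
  p_out <- band_power_fraction(y, rate, 49.75, 50.25) * sum((y - mean(y))^2)
  expect_lt(p_out / p_in, 0.01)
})
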