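test_that("age sampling honours degenerate and configured proportions", {
  expect_identical(sample_ages(100, 11L, 1, seed = 5), rep(11L, 100))
  props <- c(0.1223, 0.1061, 0.1361, 0.1348, 0.1311, 0.1286, 0.1099,
             0.1311)
  ages <- sample_ages(801, 11:18, props, seed = 1)
  expect_length(ages, 801)
  expect_true(all(ages %in% 11:18))
  # expected count at age 11 is 0.1223 * 801 ~ 98
  expect_equal(sum(ages == 11), 0.1223 * 801, tolerance = 0.35)
})

test_that("empirical age frequencies sit inside exact binomial 99% bounds", {
  props <- c(0.1223, 0.1061, 0.1361, 0.1348, 0.1311, 0.1286, 0.1099,
             0.1311)
  n <- 1e5
  ages <- sample_ages(n, 11:18, props, seed = 42)
  counts <- tabulate(ages - 10L, nbins = 8)
  expect_identical(sum(counts), as.integer(n))
  for (i in 1:8) {
    expect_gte(counts[i], qbinom(0.005, n, props[i]))
    expect_lte(counts[i], qbinom(0.995, n, props[i]))
  }
})

test_that("invalid sampling inputs are rejected", {
  expect_error(sample_ages(10, 11:12, c(0.6, 0.5)), "sum to 1")
  expect_error(sample_ages(0, 11L, 1), "positive count")
  expect_error(cohort_config(age_proportions = rep(0.2, 8)), "sum to 1")
  expect_error(cohort_config(mhr_residual_sd = -1), "nonnegative")
  expect_error(cohort_config(bccg_anchors = list(
    mhr = data.frame(age = 11, L = 1, M = -5, S = 0.03))), "positive")
})

test_that("cohort generation is reproducible and structurally sound", {
  cfg <- cohort_config(n_players = 500, seed = 31)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_identical(nrow(a), 500L)
  expect_true(all(a$mhr_bpm > a$rhr_bpm))
  expect_true(all(a$rhr_bpm > 0))
  expect_true(all(a$height_m > 0 & a$body_mass_kg > 0))
  expect_true(all(as.matrix(a[grep("skinfold", names(a))]) > 0))
  # substreams are independent of one another: a different measure label
  # leaves the age draw untouched
  cfg2 <- cohort_config(n_players = 500, seed = 31,
                        bccg_anchors = list(rhr = rhr_anchors_bccg()))
  expect_identical(generate_cohort(cfg2)$age, a$age)
  expect_identical(generate_cohort(cfg2)$mhr_bpm, a$mhr_bpm)
})

test_that("noiseless configuration reproduces the linear MHR model", {
  cfg <- cohort_config(n_players = 200, mhr_residual_sd = 0, seed = 8)
  co <- generate_cohort(cfg)
  expect_equal(co$mhr_bpm, 225.08 - 1.55 * co$age, tolerance = 1e-12)
})

test_that("the age-11 MHR mean matches the linear model", {
  cfg <- cohort_config(n_players = 1e5, age_levels = 11L,
                       age_proportions = 1,
                       rhr_anchors = data.frame(age = 11, median = 73.86),
                       anthro_params = default_anthro_params(11L),
                       seed = 12)
  co <- generate_cohort(cfg)
  # 225.08 - 1.55 * 11 = 208.03, central-limit bound 3 * 5.22 / sqrt(n)
  expect_equal(mean(co$mhr_bpm), 208.03,
               tolerance = 3 * 5.22 / sqrt(1e5) / 208.03)
})

test_that("BCCG-anchored RHR reproduces the anchored median", {
  cfg <- cohort_config(n_players = 2e4, age_levels = 11L,
                       age_proportions = 1,
                       anthro_params = default_anthro_params(11L),
                       bccg_anchors = list(rhr = rhr_anchors_bccg()),
                       seed = 4)
  co <- generate_cohort(cfg)
  se_med <- 1.2533 * 73.86 * 0.08 / sqrt(2e4)
  expect_equal(median(co$rhr_bpm), 73.86, tolerance = 3 * se_med / 73.86)
})

test_that("ages without anchors raise a configuration error", {
  cfg <- cohort_config(n_players = 200, age_levels = 10:18,
                       age_proportions = rep(1 / 9, 9),
                       anthro_params = default_anthro_params(10:18),
                       seed = 2)
  expect_error(generate_cohort(cfg), "RHR anchors")
})
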