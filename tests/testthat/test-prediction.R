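test_that("OLS is exact on noiseless affine data", {
  f <- fit_ols(c(0, 1, 2), data.frame(x = c(0, 1, 2)))
  expect_equal(unname(coef(f)), c(0, 1), tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_equal(f$see, 0, tolerance = 1e-9)

  co <- generate_cohort(cohort_config(n_players = 300,
                                      mhr_residual_sd = 0, seed = 22))
  f2 <- fit_ols(co$mhr_bpm, data.frame(age = co$age))
  expect_equal(unname(coef(f2)), c(225.08, -1.55), tolerance = 1e-9)
  expect_equal(f2$r_squared, 1, tolerance = 1e-9)
})

test_that("reported statistics satisfy their defining identities", {
  co <- generate_cohort(cohort_config(n_players = 400, seed = 23))
  f <- fit_ols(co$mhr_bpm, data.frame(age = co$age))
  # mean in-sample residual is zero with an intercept
  expect_equal(mean(residuals(f)), 0, tolerance = 1e-9)
  # R^2 equals squared Pearson correlation of fitted vs response
  expect_equal(f$r_squared,
               pearson_r(predict(f), co$mhr_bpm)^2, tolerance = 1e-9)
  # SEE uses the n - p - 1 denominator (matches lm's residual sigma)
  expect_equal(f$see, summary(f$fit)$sigma, tolerance = 1e-12)
  expect_equal(f$residual_range, range(residuals(f)))
  expect_true(f$r_squared >= 0 && f$r_squared <= 1)
})

test_that("degenerate designs and responses are rejected", {
  expect_error(fit_ols(rep(5, 10), data.frame(x = 1:10)), "degenerate")
  expect_error(fit_ols(rnorm(10), data.frame(a = 1:10, b = 2 * (1:10))),
               "singular")
  expect_error(fit_ols(c(1, 2), data.frame(x = c(1, 2))), "n >")
})

test_that("stepwise keeps a strong predictor and screens out noise", {
  picked_strong <- 0L; picked_noise <- 0L
  for (s in 1:20) {
    set.seed(300 + s)
    n <- 200
    strong <- rnorm(n)
    noise <- rnorm(n)
    y <- 2 * strong + rnorm(n)
    sw <- stepwise_select(y, data.frame(strong = strong, noise = noise))
    picked_strong <- picked_strong + ("strong" %in% sw$selected)
    picked_noise <- picked_noise + ("noise" %in% sw$selected)
  }
  expect_identical(picked_strong, 20L)   # selection frequency > 95%
  expect_lte(picked_noise, 3L)           # ~5% type-I entry rate
})

test_that("all-noise candidate pools usually yield the empty model", {
  empty <- sapply(1:40, function(s) {
    set.seed(400 + s)
    y <- rnorm(150)
    sw <- stepwise_select(y, data.frame(a = rnorm(150), b = rnorm(150)))
    length(sw$models) == 0
  })
  # two candidates at p_enter = 0.05 -> empty in roughly 90% of runs
  expect_gte(mean(empty), 0.8)
  set.seed(401)
  sw <- stepwise_select(rnorm(150), data.frame(a = rnorm(150)))
  if (!length(sw$models)) expect_identical(sw$trace$action[1], "none")
})

test_that("an age-linked BMI effect produces the two-model sequence", {
  # the BMI partial effect is moderate, so entry is assessed over seeds
  fits <- lapply(26:35, function(s) {
    cfg <- cohort_config(mhr_intercept = 228.03, mhr_age_slope = -1.45,
                         mhr_bmi_slope = -0.21, seed = s)
    co <- add_anthropometry(generate_cohort(cfg))
    stepwise_select(co$mhr_bpm, co[c("age", "bmi", "trainability")])
  })
  with_bmi <- vapply(fits, function(sw) "bmi" %in% sw$selected, logical(1))
  expect_gte(sum(with_bmi), 6L)
  sw <- fits[[which(with_bmi)[1]]]
  expect_identical(sw$models[[1]]$predictor_names, "age")
  expect_true("bmi" %in% sw$models[[2]]$predictor_names)
  expect_identical(sw$trace$variable[sw$trace$action == "enter"][1:2],
                   c("age", "bmi"))
})

test_that("published equations evaluate to their printed arithmetic", {
  expect_equal(evaluate_equation("fox", age = 20), 200)
  expect_equal(evaluate_equation("tanaka", age = 20), 194)
  expect_equal(evaluate_equation("model1", age = 11), 208.03,
               tolerance = 1e-12)
  expect_equal(evaluate_equation("model2", age = 15, bmi = 20), 202.08,
               tolerance = 1e-12)
  expect_equal(evaluate_equation("custom", age = 10,
                                 coefficients = c(intercept = 200,
                                                  age = -1)), 190)
  expect_error(evaluate_equation("model2", age = 15), "bmi")
  expect_error(evaluate_equation("model1", age = -3), "positive")
})

test_that("Bland-Altman statistics satisfy their defining identities", {
  x <- rnorm(60, 200, 6)
  ba <- bland_altman(x, x)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$loa_lower, ba$loa_upper), c(0, 0))
  set.seed(28)
  y <- x + rnorm(60, 1, 2)
  ab <- bland_altman(x, y)
  ba2 <- bland_altman(y, x)
  expect_equal(ab$bias, -ba2$bias)
  expect_equal(ab$loa_lower, -ba2$loa_upper)
  expect_equal(ab$loa_upper - ab$loa_lower, 2 * 1.96 * ab$sd_diff,
               tolerance = 1e-9)
  expect_true(ab$loa_lower <= ab$bias && ab$bias <= ab$loa_upper)
  expect_error(bland_altman(1:5, 1:4), "equal length")
})

test_that("refit model is unbiased; Fox and Tanaka err in fixed directions", {
  co <- generate_cohort(cohort_config(seed = 29))
  refit <- fit_ols(co$mhr_bpm, data.frame(age = co$age))
  expect_lt(abs(bland_altman(co$mhr_bpm, predict(refit))$bias), 0.5)
  # measured - predicted convention: Fox predicts high here, Tanaka low
  expect_lt(bland_altman(co$mhr_bpm,
                         evaluate_equation("fox", co$age))$bias, 0)
  expect_gt(bland_altman(co$mhr_bpm,
                         evaluate_equation("tanaka", co$age))$bias, 0)
})

test_that("Pearson correlation handles exact and hand-computed cases", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(2, 1, 3)), 0.5, tolerance = 1e-12)
  expect_error(pearson_r(1:3, rep(1, 3)), "constant")
  expect_error(pearson_r(1:2, 1:2), "length")
})

test_that("successive-age comparisons apply the Bonferroni correction", {
  set.seed(30)
  null_vals <- rep(rnorm(20, 100, 5), 3)
  null_groups <- rep(11:13, each = 20)
  gc0 <- group_compare(null_vals, null_groups)
  expect_lt(gc0$f_value, 1e-9)
  expect_true(all(gc0$comparisons$p_adj == 1))

  vals <- c(rnorm(30, 100, 2), rnorm(30, 110, 2))  # 5 SD shift
  gc1 <- group_compare(vals, rep(11:12, each = 30))
  expect_lt(gc1$comparisons$p_adj[1], 0.001)

  co <- generate_cohort(cohort_config(seed = 33))
  gc2 <- group_compare(co$mhr_bpm, co$age)
  expect_identical(nrow(gc2$comparisons), 7L)
  expect_true(all(gc2$comparisons$p_adj >= gc2$comparisons$p_raw))
  expect_true(all(gc2$comparisons$p_adj <= 1))
  expect_error(group_compare(c(1, 2, 3), c(11, 12, 12)), "singleton")
})
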