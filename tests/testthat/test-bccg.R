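test_that("centile formula reduces to the Gaussian and median cases", {
  # L = 1 makes the transform affine: x = M (1 + S z)
  expect_equal(bccg_centile(L = 1, M = 100, S = 0.05, alpha = 0.975),
               100 * (1 + 0.05 * qnorm(0.975)), tolerance = 1e-12)
  expect_equal(round(bccg_centile(1, 100, 0.05, 0.975), 2), 109.80)
  # alpha = 0.5 maps to M for any skewness power
  for (L in c(-2, -0.5, 0, 0.7, 2))
    expect_equal(bccg_centile(L, 123.4, 0.07, alpha = 0.5), 123.4,
                 tolerance = 1e-12)
})

test_that("z-score is the exact inverse of the centile over the grid", {
  for (L in seq(-2, 2, by = 0.5))
    for (alpha in c(0.03, 0.10, 0.25, 0.50, 0.75, 0.90, 0.97)) {
      x <- bccg_centile(L, M = 200, S = 0.05, alpha = alpha)
      expect_equal(bccg_zscore(x, L, 200, 0.05), qnorm(alpha),
                   tolerance = 1e-9)
    }
  # affine special cases
  expect_equal(bccg_zscore(200, 1, 200, 0.05), 0)
  expect_equal(bccg_zscore(200 * 1.05, 1, 200, 0.05), 1, tolerance = 1e-12)
})

test_that("the log-normal limit is continuous in L", {
  near0 <- bccg_centile(1e-8, 200, 0.03, alpha = 0.97)
  exact0 <- 200 * exp(0.03 * qnorm(0.97))
  expect_equal(near0 / exact0, 1, tolerance = 1e-6)
  expect_equal(bccg_zscore(210, 1e-8, 200, 0.03),
               log(210 / 200) / 0.03, tolerance = 1e-6)
})

test_that("infeasible tails and invalid parameters raise errors", {
  expect_error(bccg_centile(2, 100, 0.5, alpha = 0.001), "infeasible")
  expect_error(bccg_centile(1, -5, 0.1), "positive")
  expect_error(bccg_centile(1, 100, 0), "positive")
  expect_error(bccg_zscore(-1, 1, 100, 0.1), "positive")
  expect_error(rbccg(10, 1, 100, -0.1), "positive")
})

test_that("random draws follow the closed-form quantiles", {
  set.seed(101)
  n <- 1e5
  x <- rbccg(n, L = 0.2, M = 200, S = 0.03)
  # L = 1 is exactly Gaussian with mean M and SD M*S
  set.seed(102)
  g <- rbccg(n, L = 1, M = 100, S = 0.05)
  expect_equal(mean(g), 100, tolerance = 3 * 5 / sqrt(n))
  expect_equal(sd(g), 5, tolerance = 3 * 5 / sqrt(2 * n))
  # empirical 97th percentile vs closed form, within 3 asymptotic SEs
  q97 <- bccg_centile(0.2, 200, 0.03, alpha = 0.97)
  dq <- (bccg_centile(0.2, 200, 0.03, alpha = 0.9701) -
         bccg_centile(0.2, 200, 0.03, alpha = 0.9699)) / 2e-4
  se <- sqrt(0.97 * 0.03 / n) * dq
  expect_equal(unname(quantile(x, 0.97)), q97, tolerance = 3 * se / q97)
  # sample median converges to M for any L
  for (L in c(-1, 0, 1.5)) {
    set.seed(200 + L * 10)
    m <- median(rbccg(2e4, L, 150, 0.06))
    expect_equal(m, 150, tolerance = 3 * 1.2533 * 150 * 0.06 / sqrt(2e4) / 150)
  }
})

test_that("z-scores of BCCG draws are standard normal (KS at 1%)", {
  set.seed(77)
  x <- rbccg(1e4, L = 0.5, M = 200, S = 0.05)
  z <- bccg_zscore(x, 0.5, 200, 0.05)
  D <- suppressWarnings(ks.test(z, pnorm)$statistic)
  expect_lt(unname(D), 1.628 / sqrt(1e4))  # 1% critical value
})

test_that("ML fitting recovers the generating parameters (seed-averaged)", {
  # With S = 0.03 the skewness information is weak, so L is assessed on
  # the average of 10 independent fits at n = 10^4 (3 x SE of the mean).
  est <- t(sapply(1:10, function(s) {
    set.seed(s)
    coef(fit_bccg(rbccg(1e4, L = 0.5, M = 200, S = 0.03)))
  }))
  expect_equal(mean(est[, "L"]), 0.5, tolerance = 0.25 / 0.5)
  expect_equal(mean(est[, "M"]), 200, tolerance = 0.1 / 200)
  expect_equal(mean(est[, "S"]), 0.03, tolerance = 5e-4 / 0.03)
})

test_that("log-normal data yield a fitted L near zero", {
  estL <- sapply(1:5, function(s) {
    set.seed(100 + s)
    fit_bccg(rbccg(1e4, L = 0, M = 100, S = 0.1))$L
  })
  expect_lt(abs(mean(estL)), 0.15)
})

test_that("the fitted optimum beats a brute-force likelihood grid", {
  for (case in list(c(0.5, 200, 0.03), c(-1, 80, 0.1))) {
    set.seed(11 + case[1])
    x <- rbccg(500, case[1], case[2], case[3])
    fit <- fit_bccg(x)
    best <- ref_bccg_loglik(x, fit$L, fit$M, fit$S)
    expect_equal(best, fit$loglik, tolerance = 1e-8)
    grid <- expand.grid(L = fit$L + seq(-0.6, 0.6, length.out = 21),
                        logM = log(fit$M) + seq(-0.02, 0.02,
                                                length.out = 21),
                        logS = log(fit$S) + seq(-0.1, 0.1,
                                                length.out = 21))
    ll <- mapply(function(L, lM, lS) ref_bccg_loglik(x, L, exp(lM),
                                                     exp(lS)),
                 grid$L, grid$logM, grid$logS)
    expect_gte(best, max(ll) - 1e-6)
  }
})

test_that("degenerate and undersized samples are rejected", {
  expect_error(fit_bccg(rep(5, 100)), "degenerate")
  expect_error(fit_bccg(rnorm(10, 100, 5)), "at least 20")
  expect_error(fit_bccg(c(-1, rnorm(50, 100, 5))), "positive")
})
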