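#' Ordinary least squares with regression-report statistics
#'
#' Fits a linear model of a response on one or more predictors (via
#' [stats::lm()]) and reports the quantities conventional in the
#' prediction-equation literature: coefficients, coefficient of
#' determination R^2, the standard error of the estimate
#' `SEE = sqrt(SSE / (n - p - 1))` with `p` predictors, and the in-sample
#' residual range.
#'
#' @param response numeric response values.
#' @param predictors data frame (or named list) of numeric predictor
#'   columns.
#' @return An object of class `"hr_ols"` with elements `coefficients`,
#'   `predictor_names`, `r_squared`, `see`, `residual_range`, `n` and the
#'   underlying `lm` fit (`$fit`).
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' fit_ols(cohort$mhr_bpm, data.frame(age = cohort$age))
#' @seealso [stepwise_select()], [evaluate_equation()]
#' @export
fit_ols <- function(response, predictors) {
  predictors <- as.data.frame(predictors)
  n <- length(response)
  p <- ncol(predictors)
  if (nrow(predictors) != n)
    stop("'response' and 'predictors' must have equal length", call. = FALSE)
  if (n <= p + 1)
    stop("need n > number of predictors + 1", call. = FALSE)
  if (stats::var(response) == 0)
    stop("degenerate response: zero variance", call. = FALSE)
  dat <- cbind(.response = response, predictors)
  fit <- stats::lm(.response ~ ., data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("singular design: predictors are linearly dependent",
         call. = FALSE)
  res <- stats::residuals(fit)
  sse <- sum(res^2)
  sst <- sum((response - mean(response))^2)
  structure(list(coefficients = stats::coef(fit),
                 predictor_names = names(predictors),
                 r_squared = 1 - sse / sst,
                 see = sqrt(sse / (n - p - 1)),
                 residual_range = range(res),
                 n = n,
                 fit = fit),
            class = "hr_ols")
}

#' @export
print.hr_ols <- function(x, ...) {
  cat("Linear prediction model (n =", x$n, ")\n  ")
  cf <- x$coefficients
  cat(sprintf("%.3f", cf[1]),
      paste(sprintf("%+.3f*%s", cf[-1], names(cf)[-1]), collapse = " "), "\n")
  cat(sprintf("  R^2 = %.3f   SEE = %.3f   residual range [%.2f, %.2f]\n",
              x$r_squared, x$see, x$residual_range[1], x$residual_range[2]))
  invisible(x)
}

#' @export
coef.hr_ols <- function(object, ...) object$coefficients

#' @export
predict.hr_ols <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  stats::predict(object$fit, newdata = as.data.frame(newdata))
}

#' @export
residuals.hr_ols <- function(object, ...) stats::residuals(object$fit)

#' @export
summary.hr_ols <- function(object, ...) summary(object$fit)

#' Stepwise predictor selection by partial-F p-values
#'
#' Classic forward-entry / backward-removal stepwise selection: at each
#' step the candidate whose partial F-test (against the current model) has
#' the smallest p-value enters if that p-value is below `p_enter`; after
#' each entry, included predictors whose removal p-value exceeds
#' `p_remove` are dropped (largest first).  Returns the model sequence —
#' the fitted model after each successful entry — mirroring how
#' "Model 1, Model 2, ..." tables are built.
#'
#' @param response numeric response values.
#' @param candidates data frame of candidate predictor columns.
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10); must be
#'   `>= p_enter`.
#' @return An object of class `"stepwise_fit"`: a list with `models` (a
#'   list of [fit_ols()] objects, possibly empty when no candidate
#'   enters), `selected` (final predictor names) and `trace` (a data frame
#'   of steps with action, variable and p-value).
#' @examples
#' cohort <- add_anthropometry(generate_cohort(cohort_config(seed = 1)))
#' sw <- stepwise_select(cohort$mhr_bpm,
#'                       cohort[c("age", "bmi", "body_fat_pct")])
#' sw$trace
#' @export
stepwise_select <- function(response, candidates, p_enter = 0.05,
                            p_remove = 0.10) {
  if (p_enter > p_remove)
    stop("'p_enter' must be <= 'p_remove'", call. = FALSE)
  candidates <- as.data.frame(candidates)
  dat <- cbind(.response = response, candidates)
  vars <- names(candidates)
  included <- character(0)
  trace <- data.frame(step = integer(0), action = character(0),
                      variable = character(0), p_value = numeric(0))
  models <- list()
  step_no <- 0L

  fit_on <- function(v) {
    f <- if (length(v)) stats::reformulate(v, ".response")
         else .response ~ 1
    stats::lm(f, data = dat)
  }
  partial_p <- function(small, big) {
    a <- stats::anova(small, big)
    a[["Pr(>F)"]][2]
  }

  repeat {
    pool <- setdiff(vars, included)
    if (!length(pool)) break
    cur <- fit_on(included)
    ps <- vapply(pool, function(v)
      partial_p(cur, fit_on(c(included, v))), numeric(1))
    best <- which.min(ps)
    if (!is.finite(ps[best]) || ps[best] >= p_enter) break
    step_no <- step_no + 1L
    included <- c(included, pool[best])
    trace <- rbind(trace, data.frame(step = step_no, action = "enter",
                                     variable = pool[best],
                                     p_value = ps[best]))
    # backward pass
    repeat {
      if (length(included) < 2L) break
      full <- fit_on(included)
      rp <- vapply(included, function(v)
        partial_p(fit_on(setdiff(included, v)), full), numeric(1))
      worst <- which.max(rp)
      if (rp[worst] <= p_remove) break
      trace <- rbind(trace, data.frame(step = step_no, action = "remove",
                                       variable = included[worst],
                                       p_value = rp[worst]))
      included <- setdiff(included, included[worst])
    }
    models[[length(models) + 1L]] <- fit_ols(response, candidates[included])
  }
  if (!length(models))
    trace <- rbind(trace, data.frame(step = 0L, action = "none",
                                     variable = NA_character_,
                                     p_value = NA_real_))
  structure(list(models = models, selected = included, trace = trace,
                 p_enter = p_enter, p_remove = p_remove),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("Stepwise selection (p_enter =", x$p_enter,
      ", p_remove =", x$p_remove, ")\n")
  if (!length(x$models)) {
    cat("  no candidate entered the model\n")
  } else {
    for (i in seq_along(x$models)) {
      cat(sprintf("Model %d:\n", i)); print(x$models[[i]])
    }
  }
  invisible(x)
}

# Published and refitted MHR prediction equations (intercept + slopes).
hr_equations <- list(
  model1 = c(intercept = 225.08, age = -1.55),
  model2 = c(intercept = 228.03, age = -1.45, bmi = -0.21),
  fox    = c(intercept = 220,    age = -1),
  tanaka = c(intercept = 208,    age = -0.7)
)

#' Evaluate an MHR prediction equation
#'
#' Affine age (and optionally BMI) based predictors of maximum heart rate:
#' the two models developed for adolescent soccer players
#' (`model1`: `225.08 - 1.55*age`; `model2`:
#' `228.03 - 1.45*age - 0.21*BMI`), the Fox equation (`220 - age`), the
#' Tanaka equation (`208 - 0.7*age`), or custom coefficients.
#'
#' @param equation one of `"model1"`, `"model2"`, `"fox"`, `"tanaka"`, or
#'   `"custom"` (then supply `coefficients`).
#' @param age age(s) in years, positive.
#' @param bmi body mass index (kg/m^2); required by equations with a
#'   `bmi` coefficient.
#' @param coefficients named vector `c(intercept = , age = , bmi = )` for
#'   `equation = "custom"` (the `bmi` term is optional).
#' @return Predicted MHR in bpm.
#' @examples
#' evaluate_equation("fox", age = 20)      # 200
#' evaluate_equation("tanaka", age = 20)   # 194
#' evaluate_equation("model2", age = 15, bmi = 20)
#' @export
evaluate_equation <- function(equation = c("model1", "model2", "fox",
                                           "tanaka", "custom"),
                              age, bmi = NULL, coefficients = NULL) {
  equation <- match.arg(equation)
  cf <- if (equation == "custom") {
    if (is.null(coefficients) || !all(c("intercept", "age") %in%
                                      names(coefficients)))
      stop("custom equations need named 'coefficients' with at least ",
           "'intercept' and 'age'", call. = FALSE)
    coefficients
  } else hr_equations[[equation]]
  if (any(age <= 0)) stop("'age' must be positive", call. = FALSE)
  out <- cf[["intercept"]] + cf[["age"]] * age
  if ("bmi" %in% names(cf)) {
    if (is.null(bmi))
      stop(sprintf("equation '%s' requires 'bmi'", equation), call. = FALSE)
    out <- out + cf[["bmi"]] * bmi
  }
  unname(out)
}

#' Bland-Altman agreement statistics
#'
#' Quantifies agreement between measured and predicted values through the
#' paired differences `measured - predicted` (so an equation that predicts
#' too low yields a positive bias): the bias is their mean, `sd_diff`
#' their sample SD (denominator `n - 1`), and the 95% limits of agreement
#' are `bias +/- 1.96 * sd_diff`.
#'
#' `agreement_stats()` builds the same object directly from a known
#' (bias, SD) pair, e.g. to reconstruct published limits.
#'
#' @param measured,predicted numeric vectors of equal length (at least 2).
#' @param bias mean difference.
#' @param sd_diff SD of the differences, nonnegative.
#' @param n optional sample size for the record.
#' @return An object of class `"agreement_stats"` with elements `bias`,
#'   `sd_diff`, `loa_lower`, `loa_upper`, `n`.
#' @examples
#' agreement_stats(bias = 0.003, sd_diff = 5.22)
#' x <- rnorm(50, 200, 5); bland_altman(x, x - 2)
#' @export
bland_altman <- function(measured, predicted) {
  if (length(measured) != length(predicted))
    stop("'measured' and 'predicted' must have equal length", call. = FALSE)
  if (length(measured) < 2L)
    stop("need at least 2 paired values", call. = FALSE)
  d <- measured - predicted
  agreement_stats(mean(d), stats::sd(d), n = length(d))
}

#' @rdname bland_altman
#' @export
agreement_stats <- function(bias, sd_diff, n = NA_integer_) {
  if (sd_diff < 0) stop("'sd_diff' must be nonnegative", call. = FALSE)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_lower = bias - 1.96 * sd_diff,
                 loa_upper = bias + 1.96 * sd_diff,
                 n = n),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: bias %+.3f, SD %.3f, 95%% LoA [%+.2f, %+.2f]%s\n",
    x$bias, x$sd_diff, x$loa_lower, x$loa_upper,
    if (is.na(x$n)) "" else sprintf(" (n = %d)", x$n)))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] that enforces the preconditions used
#' throughout the analysis: equal lengths of at least 3 and nonconstant
#' inputs.
#'
#' @param x,y numeric vectors.
#' @return Correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson_r(1:10, 2 * (1:10) + 1)
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("'x' and 'y' must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: constant vector", call. = FALSE)
  stats::cor(x, y)
}

#' One-way ANOVA with Bonferroni-adjusted successive-group comparisons
#'
#' Standard one-way analysis of variance across integer age groups,
#' followed by pooled-variance t-tests for each pair of *consecutive*
#' ages, Bonferroni-adjusted by multiplying the raw p-value by the number
#' of successive comparisons (capped at 1).  This mirrors the
#' between-successive-age-groups comparison structure of descriptive
#' cohort tables.
#'
#' @param values numeric measurements.
#' @param groups integer group labels (ages), one per value; at least two
#'   groups with at least two members each.
#' @return An object of class `"group_compare"` with `f_value`, `p_value`
#'   (ANOVA), and `comparisons`, a data frame with one row per successive
#'   age pair (`group1`, `group2`, `diff`, `p_raw`, `p_adj`).
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' group_compare(cohort$mhr_bpm, cohort$age)
#' @export
group_compare <- function(values, groups) {
  if (length(values) != length(groups))
    stop("'values' and 'groups' must have equal length", call. = FALSE)
  counts <- table(groups)
  if (length(counts) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(counts < 2L))
    stop("every group needs at least 2 members; singleton group(s): ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  g <- factor(groups)
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  mse <- tab["Residuals", "Mean Sq"]
  dfres <- tab["Residuals", "Df"]

  lev <- sort(unique(as.numeric(as.character(levels(g)))))
  k <- length(lev) - 1L  # number of successive comparisons
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  cmp <- do.call(rbind, lapply(seq_len(k), function(i) {
    a <- as.character(lev[i]); b <- as.character(lev[i + 1])
    diff <- means[[a]] - means[[b]]
    se <- sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
    p <- 2 * stats::pt(abs(diff / se), dfres, lower.tail = FALSE)
    data.frame(group1 = lev[i], group2 = lev[i + 1], diff = diff,
               p_raw = p, p_adj = min(1, p * k))
  }))
  structure(list(f_value = tab["g", "F value"],
                 p_value = tab["g", "Pr(>F)"],
                 comparisons = cmp, aov = fit),
            class = "group_compare")
}

#' @export
print.group_compare <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.3g\n", x$f_value, x$p_value))
  cat("Successive-group comparisons (Bonferroni-adjusted):\n")
  print(x$comparisons, digits = 4, row.names = FALSE)
  invisible(x)
}
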