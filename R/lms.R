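#' Fit LMS (Box-Cox Cole-Green) reference centile curves across age
#'
#' The central fitting function of the package.  An LMS reference curve
#' represents the age-conditional distribution of a measurement by three
#' curves: the Box-Cox power `L` (skewness), the median `M` and the
#' coefficient of variation `S`.  Fitting proceeds in two testable stages:
#'
#' 1. **Per-age maximum likelihood.**  Each integer age group is fitted
#'    separately by [fit_bccg()].
#' 2. **Smoothing across age.**  Each of the three parameter sequences is
#'    smoothed by a cubic smoothing spline ([stats::smooth.spline()]) with
#'    a configurable equivalent degrees of freedom per component
#'    (defaults `L = 3`, `M = 5`, `S = 3`).  `M` and `S` are smoothed on
#'    the log scale so positivity is preserved.  Smoothing is skipped when
#'    `df` is `NULL` or when fewer than four age groups are available.
#'
#' @param cohort data frame with an `age` column and the measurement
#'   column named by `measure`.
#' @param measure name of the measurement column (e.g. `"mhr_bpm"`).
#' @param ages ages to fit; defaults to all ages present.
#' @param df equivalent degrees of freedom for the `L`, `M`, `S` smoothing
#'   splines (named or positional length-3 vector), or `NULL` to disable
#'   smoothing.
#' @param min_n minimum group size passed to [fit_bccg()].
#' @return An object of class `"lms_curve"`: the smoothed per-age `L`,
#'   `M`, `S` values (`coef()` returns them as an age-by-parameter
#'   matrix), the raw per-age fits, and the smoothing specification.
#' @examples
#' cfg <- cohort_config(n_players = 400, seed = 2)
#' curve <- lms_fit(generate_cohort(cfg), "mhr_bpm")
#' curve
#' centile_table(curve)
#' @seealso [centile_table()], [predict.lms_curve()], [decline_summary()]
#' @export
lms_fit <- function(cohort, measure, ages = NULL,
                    df = c(L = 3, M = 5, S = 3), min_n = 20L) {
  if (!measure %in% names(cohort))
    stop(sprintf("column '%s' not found in cohort", measure), call. = FALSE)
  if (!"age" %in% names(cohort))
    stop("cohort must have an 'age' column", call. = FALSE)
  if (is.null(ages)) ages <- sort(unique(cohort$age))
  ages <- as.integer(ages)

  fits <- vector("list", length(ages))
  for (i in seq_along(ages)) {
    x <- cohort[[measure]][cohort$age == ages[i]]
    fits[[i]] <- tryCatch(
      fit_bccg(x, min_n = min_n),
      error = function(e) stop(sprintf("age %d: %s", ages[i],
                                       conditionMessage(e)), call. = FALSE))
  }
  raw <- t(vapply(fits, coef, numeric(3)))
  rownames(raw) <- ages

  smoothed <- raw
  do_smooth <- !is.null(df) && length(ages) >= 4L
  if (do_smooth) {
    if (length(df) != 3L) stop("'df' must have three entries", call. = FALSE)
    df <- stats::setNames(as.numeric(df), c("L", "M", "S"))
    dfc <- pmin(pmax(df, 1), length(ages))  # spline df bounded by #ages
    smoothed[, "L"] <- stats::predict(
      stats::smooth.spline(ages, raw[, "L"], df = dfc["L"]), ages)$y
    smoothed[, "M"] <- exp(stats::predict(
      stats::smooth.spline(ages, log(raw[, "M"]), df = dfc["M"]), ages)$y)
    smoothed[, "S"] <- exp(stats::predict(
      stats::smooth.spline(ages, log(raw[, "S"]), df = dfc["S"]), ages)$y)
  }

  structure(list(measure = measure, ages = ages, lms = smoothed,
                 raw = raw, fits = fits,
                 smoothing = list(enabled = do_smooth,
                                  method = "cubic smoothing spline",
                                  df = if (do_smooth) df else NULL),
                 n_by_age = vapply(fits, function(f) f$n, integer(1)),
                 call = match.call()),
            class = "lms_curve")
}

#' @export
print.lms_curve <- function(x, digits = 4, ...) {
  cat("LMS reference curve for", x$measure, "\n")
  cat("  ages", paste(range(x$ages), collapse = "-"), "|",
      if (x$smoothing$enabled)
        sprintf("spline-smoothed (df L=%g, M=%g, S=%g)",
                x$smoothing$df["L"], x$smoothing$df["M"], x$smoothing$df["S"])
      else "unsmoothed", "\n")
  print(round(coef(x), digits))
  invisible(x)
}

#' @export
summary.lms_curve <- function(object, ...) {
  tab <- data.frame(age = object$ages, n = object$n_by_age,
                    coef(object),
                    L_raw = object$raw[, "L"], M_raw = object$raw[, "M"],
                    S_raw = object$raw[, "S"], row.names = NULL)
  structure(list(measure = object$measure, table = tab,
                 smoothing = object$smoothing), class = "summary.lms_curve")
}

#' @export
print.summary.lms_curve <- function(x, ...) {
  cat("LMS curve summary:", x$measure, "\n")
  print(x$table, digits = 5)
  invisible(x)
}

#' @export
coef.lms_curve <- function(object, ...) object$lms

# Interpolate the smoothed L, M, S at arbitrary ages within the fitted
# range (L linear; M, S linear on the log scale).
lms_at_age <- function(object, age) {
  if (any(age < min(object$ages) | age > max(object$ages)))
    stop(sprintf("age outside fitted range %d-%d",
                 min(object$ages), max(object$ages)), call. = FALSE)
  list(L = stats::approx(object$ages, object$lms[, "L"], xout = age)$y,
       M = exp(stats::approx(object$ages, log(object$lms[, "M"]),
                             xout = age)$y),
       S = exp(stats::approx(object$ages, log(object$lms[, "S"]),
                             xout = age)$y))
}

#' Predict centiles or z-scores from a fitted LMS curve
#'
#' With `type = "centile"` returns the reference value below which a
#' fraction `alpha` of the population falls at each `age`; with
#' `type = "zscore"` converts observed measurements `x` at `age` into
#' age-standardised normal deviates.
#'
#' @param object an [lms_fit()] result.
#' @param age age(s) in years within the fitted range.
#' @param alpha centile order(s) in (0, 1), for `type = "centile"`.
#' @param x measurement value(s), for `type = "zscore"`.
#' @param type `"centile"` or `"zscore"`.
#' @param ... unused.
#' @return For `"centile"`: a numeric vector (one `age` with several
#'   `alpha`, or vectorised over `age`).  For `"zscore"`: a numeric vector
#'   of z-scores.
#' @examples
#' cfg <- cohort_config(n_players = 400, seed = 2)
#' curve <- lms_fit(generate_cohort(cfg), "mhr_bpm")
#' predict(curve, age = 12, alpha = c(0.03, 0.5, 0.97))
#' predict(curve, age = 12, x = 205, type = "zscore")
#' @export
predict.lms_curve <- function(object, age, alpha = 0.5, x = NULL,
                              type = c("centile", "zscore"), ...) {
  type <- match.arg(type)
  p <- lms_at_age(object, age)
  if (type == "centile") {
    if (length(age) == 1L)
      return(vapply(alpha, function(a)
        bccg_centile(p$L, p$M, p$S, alpha = a), numeric(1)))
    if (length(alpha) == 1L)
      return(vapply(seq_along(age), function(i)
        bccg_centile(p$L[i], p$M[i], p$S[i], alpha = alpha), numeric(1)))
    stop("vectorise over 'age' or 'alpha', not both", call. = FALSE)
  }
  if (is.null(x)) stop("'x' is required for type = 'zscore'", call. = FALSE)
  if (length(age) == 1L)
    return(vapply(x, function(v) bccg_zscore(v, p$L, p$M, p$S), numeric(1)))
  if (length(x) != length(age))
    stop("'x' and 'age' must have equal length", call. = FALSE)
  vapply(seq_along(x), function(i)
    bccg_zscore(x[i], p$L[i], p$M[i], p$S[i]), numeric(1))
}

#' Age-by-centile reference table
#'
#' Evaluates the fitted curve at every age for each requested centile
#' order.  The `alpha = 0.5` column reproduces the `M` sequence exactly,
#' and columns are strictly increasing in `alpha` at every age.
#'
#' @param curve an [lms_fit()] result.
#' @param alphas centile orders in (0, 1); the default set
#'   `{3, 10, 25, 50, 75, 90, 97}%` matches standard reference charts.
#' @return Data frame with an `age` column and one `P<k>` column per
#'   centile.
#' @examples
#' cfg <- cohort_config(n_players = 400, seed = 2)
#' centile_table(lms_fit(generate_cohort(cfg), "mhr_bpm"))
#' @export
centile_table <- function(curve,
                          alphas = c(0.03, 0.10, 0.25, 0.50, 0.75,
                                     0.90, 0.97)) {
  stopifnot(inherits(curve, "lms_curve"))
  if (any(alphas <= 0 | alphas >= 1))
    stop("'alphas' must lie strictly between 0 and 1", call. = FALSE)
  out <- data.frame(age = curve$ages)
  for (a in alphas) {
    col <- vapply(seq_along(curve$ages), function(i)
      tryCatch(bccg_centile(curve$lms[i, "L"], curve$lms[i, "M"],
                            curve$lms[i, "S"], alpha = a),
               error = function(e)
                 stop(sprintf("age %d, alpha %.3g: %s", curve$ages[i], a,
                              conditionMessage(e)), call. = FALSE)),
      numeric(1))
    out[[sprintf("P%g", 100 * a)]] <- col
  }
  out
}

#' @export
plot.lms_curve <- function(x, alphas = c(0.03, 0.10, 0.25, 0.50, 0.75,
                                         0.90, 0.97),
                           xlab = "Age (years)", ylab = x$measure,
                           main = paste("Reference centiles:", x$measure),
                           ...) {
  tab <- centile_table(x, alphas)
  graphics::matplot(tab$age, as.matrix(tab[-1]), type = "l", lty = 1,
                    col = grDevices::hcl.colors(length(alphas), "Zissou 1"),
                    xlab = xlab, ylab = ylab, main = main, ...)
  graphics::text(max(tab$age), unlist(tab[nrow(tab), -1]),
                 labels = names(tab)[-1], pos = 4, cex = 0.7, xpd = NA)
  invisible(tab)
}

#' Yearly-decline summary of a per-age reference series
#'
#' For a series of values at consecutive integer ages, computes the yearly
#' declines `d_i = v_i - v_{i+1}` (positive when the series falls), their
#' mean and sample SD, and the overall percent change
#' `100 * (v_last - v_first) / v_first`.  By construction the mean yearly
#' decline times the number of steps equals the endpoint difference
#' exactly.
#'
#' @param series numeric vector of per-age values, at least 2.
#' @param units optional unit label carried into printing.
#' @return An object of class `"decline_summary"` with elements
#'   `mean_yearly_decline`, `sd_yearly_decline` (`NA` for a 2-point
#'   series), `overall_pct_change`, `n_points`, `units`.
#' @examples
#' decline_summary(c(208.64, 196.93))     # endpoint pair
#' decline_summary(c(10, 8, 6))
#' @export
decline_summary <- function(series, units = "") {
  if (length(series) < 2L)
    stop("need at least 2 values", call. = FALSE)
  d <- -diff(series)  # v_i - v_{i+1}
  structure(list(mean_yearly_decline = mean(d),
                 sd_yearly_decline = stats::sd(d),
                 overall_pct_change =
                   100 * (series[length(series)] - series[1]) / series[1],
                 n_points = length(series), units = units),
            class = "decline_summary")
}

#' @export
print.decline_summary <- function(x, ...) {
  cat(sprintf("Decline: %.2f +/- %s %s/year over %d points; overall %+.2f%%\n",
              x$mean_yearly_decline,
              ifelse(is.na(x$sd_yearly_decline), "NA",
                     sprintf("%.2f", x$sd_yearly_decline)),
              x$units, x$n_points, x$overall_pct_change))
  invisible(x)
}
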