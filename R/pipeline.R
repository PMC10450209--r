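#' Run the full reference-curve and prediction-equation analysis
#'
#' Orchestrates the complete workflow on a synthetic or loaded cohort:
#' generate (or read) the cohort, derive anthropometrics, fit LMS
#' reference curves for maximum and resting heart rate, tabulate centiles
#' and yearly declines (P3 / P50 / P97), run stepwise selection of MHR
#' predictors, refit the age-only prediction model, and compute
#' Bland-Altman agreement of the refitted model and of the Fox and Tanaka
#' equations against the measured MHR.
#'
#' @param config a [cohort_config()] (the cohort is generated) or a file
#'   path to a cohort CSV (the cohort is loaded via [read_cohort_csv()]).
#' @param out_dir optional directory; when given, the bundle is written
#'   there as CSV tables plus a JSON provenance file and a plain-text
#'   summary (see [write_report_bundle()]).
#' @param alphas centile orders for the reference tables.
#' @param candidates predictor columns offered to [stepwise_select()].
#' @param lms_df smoothing degrees of freedom passed to [lms_fit()].
#' @param quiet suppress per-stage progress messages.
#' @return An object of class `"report_bundle"`: a list with
#'   `percentile_tables`, `lms_tables`, `decline_summaries`, `models`
#'   (stepwise sequence plus the refitted age-only model), `agreement`
#'   (per equation), `group_tests` and `provenance`.
#' @examples
#' bundle <- run_pipeline(cohort_config(n_players = 400, seed = 9),
#'                        quiet = TRUE)
#' bundle$percentile_tables$mhr_bpm
#' bundle$agreement$fox
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         alphas = c(0.03, 0.10, 0.25, 0.50, 0.75, 0.90,
                                    0.97),
                         candidates = c("age", "height_m", "body_mass_kg",
                                        "bmi", "body_fat_pct",
                                        "trainability", "rhr_bpm"),
                         lms_df = c(L = 3, M = 5, S = 3),
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message("[pipeline] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (inherits(config, "cohort_config")) {
    say("generate: n = ", config$n_players, ", seed = ", config$seed)
    cohort <- stage("generate", generate_cohort(config))
    provenance_config <- unclass(config)
    seed <- config$seed
  } else if (is.character(config) && length(config) == 1L) {
    say("load: ", config)
    cohort <- stage("load", read_cohort_csv(config))
    provenance_config <- list(source = "csv", path = config)
    seed <- NA_integer_
  } else stop("'config' must be a cohort_config or a CSV path",
              call. = FALSE)

  say("anthropometry: ", nrow(cohort), " records")
  cohort <- stage("anthropometry", add_anthropometry(cohort))

  measures <- c("mhr_bpm", "rhr_bpm")
  curves <- list(); tables <- list(); declines <- list()
  for (m in measures) {
    say("lms_fit: ", m)
    curves[[m]] <- stage(paste0("lms_fit:", m),
                         lms_fit(cohort, m, df = lms_df))
    tables[[m]] <- stage(paste0("centiles:", m),
                         centile_table(curves[[m]], alphas))
    declines[[m]] <- lapply(
      stats::setNames(c("P3", "P50", "P97"), c("P3", "P50", "P97")),
      function(col) {
        if (!col %in% names(tables[[m]])) return(NULL)
        decline_summary(tables[[m]][[col]], units = "bpm")
      })
  }

  say("stepwise regression: ", length(candidates), " candidates")
  candidates <- intersect(candidates, names(cohort))
  sw <- stage("stepwise", stepwise_select(cohort$mhr_bpm,
                                          cohort[candidates]))
  model1_refit <- stage("refit_age_model",
                        fit_ols(cohort$mhr_bpm,
                                data.frame(age = cohort$age)))

  say("agreement: refit model vs Fox vs Tanaka")
  agreement <- stage("agreement", list(
    model1 = bland_altman(cohort$mhr_bpm, predict(model1_refit)),
    fox = bland_altman(cohort$mhr_bpm,
                       evaluate_equation("fox", cohort$age)),
    tanaka = bland_altman(cohort$mhr_bpm,
                          evaluate_equation("tanaka", cohort$age))))

  say("group comparisons")
  group_tests <- stage("group_compare", lapply(
    stats::setNames(measures, measures),
    function(m) group_compare(cohort[[m]], cohort$age)))

  bundle <- structure(list(
    percentile_tables = tables,
    lms_tables = lapply(curves, function(cu)
      data.frame(age = cu$ages, cu$lms, row.names = NULL)),
    decline_summaries = declines,
    curves = curves,
    models = list(stepwise = sw, model1_refit = model1_refit),
    agreement = agreement,
    group_tests = group_tests,
    cohort = cohort,
    provenance = list(config = provenance_config, seed = seed,
                      alphas = alphas, lms_df = as.list(lms_df),
                      package_version =
                        as.character(utils::packageVersion("hrcentiles")))),
    class = "report_bundle")

  if (!is.null(out_dir)) {
    say("write: ", out_dir)
    stage("write", write_report_bundle(bundle, out_dir))
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Heart-rate reference analysis bundle\n")
  cat("  cohort:", nrow(x$cohort), "records | measures:",
      paste(names(x$percentile_tables), collapse = ", "), "\n")
  nm <- length(x$models$stepwise$models)
  cat("  stepwise models:", nm,
      if (nm) paste0("(final: ",
                     paste(x$models$stepwise$selected, collapse = " + "),
                     ")") else "", "\n")
  cat("  agreement equations:", paste(names(x$agreement), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Serialises every table of a [run_pipeline()] bundle as CSV (full
#' 17-significant-digit precision, so rounded presentation values always
#' have an unrounded counterpart on disk), the provenance as JSON, and a
#' human-readable `summary.txt`.  Output is deterministic: identical
#' bundles produce byte-identical files.
#'
#' @param bundle a `"report_bundle"`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    out <- df
    for (col in names(out))
      if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
    utils::write.csv(out, file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  for (m in names(bundle$percentile_tables))
    wr(bundle$percentile_tables[[m]], paste0("centiles_", m, ".csv"))
  for (m in names(bundle$lms_tables))
    wr(bundle$lms_tables[[m]], paste0("lms_", m, ".csv"))

  dec <- do.call(rbind, lapply(names(bundle$decline_summaries), function(m)
    do.call(rbind, lapply(names(bundle$decline_summaries[[m]]),
                          function(p) {
      d <- bundle$decline_summaries[[m]][[p]]
      if (is.null(d)) return(NULL)
      data.frame(measure = m, percentile = p,
                 mean_yearly_decline = d$mean_yearly_decline,
                 sd_yearly_decline = d$sd_yearly_decline,
                 overall_pct_change = d$overall_pct_change)
    }))))
  wr(dec, "decline_summaries.csv")

  mods <- bundle$models$stepwise$models
  mods <- c(mods, list(bundle$models$model1_refit))
  mod_df <- do.call(rbind, lapply(seq_along(mods), function(i) {
    m <- mods[[i]]
    data.frame(model = if (i <= length(mods) - 1)
                 paste0("stepwise_", i) else "model1_refit",
               predictors = paste(m$predictor_names, collapse = "+"),
               coefficients = paste(sprintf("%s=%.17g",
                                            names(m$coefficients),
                                            m$coefficients),
                                    collapse = ";"),
               r_squared = m$r_squared, see = m$see,
               resid_min = m$residual_range[1],
               resid_max = m$residual_range[2], n = m$n)
  }))
  wr(mod_df, "models.csv")

  agr <- do.call(rbind, lapply(names(bundle$agreement), function(eq) {
    a <- bundle$agreement[[eq]]
    data.frame(equation = eq, bias = a$bias, sd_diff = a$sd_diff,
               loa_lower = a$loa_lower, loa_upper = a$loa_upper, n = a$n)
  }))
  wr(agr, "agreement.csv")

  jsonlite::write_json(bundle$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  con <- file(file.path(out_dir, "summary.txt"), "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Heart-rate reference analysis summary")
  w("cohort: %d records, ages %s", nrow(bundle$cohort),
    paste(range(bundle$cohort$age), collapse = "-"))
  for (m in names(bundle$percentile_tables)) {
    tab <- bundle$percentile_tables[[m]]
    w("%s median: %.2f bpm (age %d) to %.2f bpm (age %d)", m,
      tab$P50[1], tab$age[1], tab$P50[nrow(tab)], tab$age[nrow(tab)])
  }
  refit <- bundle$models$model1_refit
  w("age-only model: MHR = %.2f %+.2f * age (R^2 = %.3f, SEE = %.2f)",
    refit$coefficients[1], refit$coefficients[2], refit$r_squared,
    refit$see)
  for (eq in names(bundle$agreement)) {
    a <- bundle$agreement[[eq]]
    w("agreement %s: bias %+.3f, SD %.2f, LoA [%+.2f, %+.2f]", eq,
      a$bias, a$sd_diff, a$loa_lower, a$loa_upper)
  }
  invisible(out_dir)
}

#' Bland-Altman scatter of one agreement comparison
#'
#' Plots differences (measured minus predicted) against their pairwise
#' means with the bias and 95% limits of agreement as horizontal lines.
#'
#' @param measured,predicted numeric vectors of equal length.
#' @param main plot title.
#' @return The [bland_altman()] statistics, invisibly.
#' @export
plot_bland_altman <- function(measured, predicted,
                              main = "Bland-Altman agreement") {
  stats <- bland_altman(measured, predicted)
  avg <- (measured + predicted) / 2
  graphics::plot(avg, measured - predicted, pch = 16, cex = 0.5,
                 col = "grey40", xlab = "Mean of methods (bpm)",
                 ylab = "Difference, measured - predicted (bpm)",
                 main = main)
  graphics::abline(h = c(stats$bias, stats$loa_lower, stats$loa_upper),
                   lty = c(1, 2, 2), col = "firebrick")
  invisible(stats)
}
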