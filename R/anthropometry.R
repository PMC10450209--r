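#' Body mass index
#'
#' Ratio of body mass (kg) to squared height (m^2).
#'
#' @param body_mass_kg body mass in kilograms, positive.
#' @param height_m height in metres, positive.
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(60, 1.5)
#' @export
compute_bmi <- function(body_mass_kg, height_m) {
  if (any(body_mass_kg <= 0)) stop("'body_mass_kg' must be positive",
                                   call. = FALSE)
  if (any(height_m <= 0)) stop("'height_m' must be positive", call. = FALSE)
  body_mass_kg / height_m^2
}

#' Body density from the sum of four skinfolds (Durnin-Womersley)
#'
#' Quadratic-in-skinfolds, linear-in-age body density:
#' \deqn{D = 1.0994921 - 0.0009929\,s + 0.0000023\,s^2 - 0.0001392\,a}
#' with \eqn{s} the sum of the triceps, biceps, subscapular and suprailiac
#' skinfolds (mm) and \eqn{a} the age in years.  Over the physiologic
#' skinfold range (roughly 10-120 mm) density decreases strictly with
#' \eqn{s}.
#'
#' @param sum_skinfolds_mm sum of the four skinfolds, mm, positive.
#' @param age_yr age in years, positive.
#' @return Body density in g/cm^3.
#' @examples
#' body_density(30, 14)
#' @export
body_density <- function(sum_skinfolds_mm, age_yr) {
  if (any(sum_skinfolds_mm <= 0))
    stop("'sum_skinfolds_mm' must be positive", call. = FALSE)
  if (any(age_yr <= 0)) stop("'age_yr' must be positive", call. = FALSE)
  1.0994921 - 0.0009929 * sum_skinfolds_mm +
    0.0000023 * sum_skinfolds_mm^2 - 0.0001392 * age_yr
}

#' Body-fat percentage from body density (Siri)
#'
#' The Siri conversion `4.95/D - 4.50` yields a body-fat *fraction*; this
#' function reports it on the percent scale (multiplied by 100), matching
#' the conventional "BF %" label.
#'
#' @param density_g_cm3 body density in g/cm^3, positive.
#' @return Body fat as a percentage.
#' @examples
#' body_fat_percent(1.0698263)
#' body_fat_percent(1.1) # exactly 0
#' @export
body_fat_percent <- function(density_g_cm3) {
  if (any(density_g_cm3 <= 0))
    stop("'density_g_cm3' must be positive", call. = FALSE)
  100 * (4.95 / density_g_cm3 - 4.50)
}

#' Append derived anthropometric columns to a cohort
#'
#' Adds `bmi` (kg/m^2), `sum_skinfolds_mm`, `density_g_cm3` and
#' `body_fat_pct` computed from the four skinfold sites and age.  All four
#' skinfold columns are required; there is no imputation of missing sites.
#'
#' @param cohort a cohort data frame as produced by [generate_cohort()] or
#'   [read_cohort_csv()].
#' @return The cohort with the four derived columns appended.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_players = 50, seed = 3))
#' head(add_anthropometry(cohort))
#' @export
add_anthropometry <- function(cohort) {
  sites <- c("skinfold_triceps_mm", "skinfold_biceps_mm",
             "skinfold_subscapular_mm", "skinfold_suprailiac_mm")
  missing <- setdiff(c(sites, "age", "height_m", "body_mass_kg"),
                     names(cohort))
  if (length(missing))
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cohort$bmi <- compute_bmi(cohort$body_mass_kg, cohort$height_m)
  cohort$sum_skinfolds_mm <- rowSums(cohort[sites])
  cohort$density_g_cm3 <- body_density(cohort$sum_skinfolds_mm, cohort$age)
  cohort$body_fat_pct <- body_fat_percent(cohort$density_g_cm3)
  cohort
}
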