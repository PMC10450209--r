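cohort_required_columns <- c("age", "height_m", "body_mass_kg",
                             "skinfold_triceps_mm", "skinfold_biceps_mm",
                             "skinfold_subscapular_mm",
                             "skinfold_suprailiac_mm",
                             "rhr_bpm", "mhr_bpm")

#' Read and validate a cohort CSV
#'
#' Expects a comma-separated, dot-decimal file with a header row carrying
#' at least the columns `age`, `height_m`, `body_mass_kg`, the four
#' skinfold columns (`skinfold_triceps_mm`, `skinfold_biceps_mm`,
#' `skinfold_subscapular_mm`, `skinfold_suprailiac_mm`), `rhr_bpm` and
#' `mhr_bpm` (units are encoded in the column names to prevent unit
#' drift).  Every required cell must be numeric, and each row must
#' satisfy the record invariants: positive height, mass and skinfolds,
#' and `mhr > rhr > 0`.  Errors name the offending column and row.
#'
#' @param path path to the CSV file.
#' @return A validated cohort data frame.
#' @seealso [write_cohort_csv()]
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_required_columns, names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in cohort_required_columns) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA")
      stop(sprintf("non-numeric value in column '%s' (row %d: \"%s\")",
                   col, bad[1], v[bad[1]]), call. = FALSE)
    }
    if (anyNA(v))
      stop(sprintf("missing value in column '%s' (row %d)",
                   col, which(is.na(v))[1]), call. = FALSE)
  }
  validate_cohort(raw)
  raw
}

# Enforce the per-record invariants; errors cite the first offending row.
validate_cohort <- function(cohort) {
  fail <- function(rows, what)
    stop(sprintf("invalid record (row %s): %s",
                 paste(utils::head(rows, 5), collapse = ", "), what),
         call. = FALSE)
  if (any(bad <- cohort$height_m <= 0)) fail(which(bad), "height_m <= 0")
  if (any(bad <- cohort$body_mass_kg <= 0))
    fail(which(bad), "body_mass_kg <= 0")
  for (col in grep("^skinfold_", cohort_required_columns, value = TRUE))
    if (any(bad <- cohort[[col]] <= 0)) fail(which(bad), paste(col, "<= 0"))
  if (any(bad <- cohort$rhr_bpm <= 0)) fail(which(bad), "rhr_bpm <= 0")
  if (any(bad <- cohort$mhr_bpm <= cohort$rhr_bpm))
    fail(which(bad), "mhr_bpm <= rhr_bpm")
  invisible(cohort)
}

#' Write a cohort to CSV at full precision
#'
#' Numeric columns are serialised with 17 significant digits so that a
#' [read_cohort_csv()] round trip restores every double bit-exactly.
#'
#' @param cohort a cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  for (col in names(out))
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
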