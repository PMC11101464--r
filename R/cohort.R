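#' Construct a cohort metadata table
#'
#' One row per sample with the demographic and adjudication metadata the
#' evaluation strata and splits need. Race is metadata only and is never
#' offered as a model feature. The adjudicated TOAST label may be 1-4
#' (determined etiologies) or 5 (cryptogenic, input only).
#'
#' @param sample_id Unique sample identifiers.
#' @param cohort Cohort/site identifier.
#' @param admission_year Integer admission year.
#' @param age Age in years.
#' @param sex `"female"` or `"male"`.
#' @param race Race stratum label or `NA`.
#' @param toast Adjudicated label in `1:5`.
#' @param latent_class Optional latent etiology (simulated cryptogenic
#'   samples only); `NA` otherwise.
#' @return A `data.frame` of class `cohort_table`.
#' @export
cohort_table <- function(sample_id, cohort, admission_year, age, sex,
                         race = NA_character_, toast,
                         latent_class = NA_integer_) {
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in cohort table")
  toast <- as.integer(toast)
  if (!all(toast %in% 1:5)) stop("toast labels must be in 1..5")
  if (!all(sex %in% c("female", "male"))) stop("sex must be female or male")
  out <- data.frame(sample_id = as.character(sample_id),
                    cohort = as.character(cohort),
                    admission_year = as.integer(admission_year),
                    age = as.numeric(age),
                    sex = as.character(sex),
                    race = rep_len(as.character(race), length(sample_id)),
                    toast = toast,
                    latent_class = rep_len(as.integer(latent_class), length(sample_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write / read a cohort table as CSV
#'
#' Metadata columns are written with the `meta_` prefix used by the
#' package's delimited-file convention. The latent class of simulated
#' cryptogenic samples is never exported.
#'
#' @param ct A `cohort_table`.
#' @param path File path.
#' @return `write_cohort_table` returns `path` invisibly;
#'   `read_cohort_table` returns a `cohort_table`.
#' @export
write_cohort_table <- function(ct, path) {
  df <- as.data.frame(ct)
  df$latent_class <- NULL
  names(df)[-1] <- paste0("meta_", names(df)[-1])
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = TRUE,
                   eol = "\r\n")
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = "",
                        stringsAsFactors = FALSE)
  names(df) <- sub("^meta_", "", names(df))
  cohort_table(df$sample_id, df$cohort, df$admission_year, df$age, df$sex,
               df$race, df$toast)
}

#' Split a cohort longitudinally by admission year
#'
#' Training samples are all admissions strictly before `test_year`; test
#' samples are the admissions of `test_year` itself. Rows after the test
#' year are not used.
#'
#' @param cohort A `cohort_table`.
#' @param test_year Integer year.
#' @return List with integer `train` and `test` row indices.
#' @export
longitudinal_split <- function(cohort, test_year) {
  yr <- cohort$admission_year
  test <- which(yr == test_year)
  if (!length(test)) stop("no samples with admission year ", test_year)
  list(train = which(yr < test_year), test = test)
}
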