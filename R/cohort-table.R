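# Subject-metadata tables: one row per subject with id, age, sex, cohort,
# scanner and a path to the subject's volume. CSV, comma-separated, UTF-8,
# header required.

.sex_aliases <- list(
  female = c("female", "f", "fem", "woman", "w"),
  male   = c("male", "m", "man")
)

#' Normalize a sex label to the two-level set
#'
#' Accepted aliases (case-insensitive): female/f/fem/woman/w and
#' male/m/man.
#'
#' @param x character vector of sex labels.
#' @return character vector with entries `"female"` or `"male"`.
#' @export
normalize_sex <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(lx))
  out[lx %in% .sex_aliases$female] <- "female"
  out[lx %in% .sex_aliases$male] <- "male"
  if (any(is.na(out)))
    an_stop(sprintf("unrecognized sex label(s): %s",
                    paste(unique(x[is.na(out)]), collapse = ", ")), "sex")
  out
}

.cohort_columns <- c("subject_id", "age", "sex", "cohort", "scanner", "volume_ref")

#' Read a cohort metadata table
#'
#' Expects a CSV with header columns `subject_id, age, sex, cohort, scanner,
#' volume_ref`. Sexes are normalized to female/male; fractional ages are
#' floored to integer years with a warning (cohort tables in this field
#' report integer ages). Distinct errors are raised for a missing column,
#' duplicate subject ids, and unparseable or out-of-range ages.
#'
#' @param path path to a CSV file.
#' @return a `data.frame` with one row per subject.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) an_stop(sprintf("no such file: %s", path), "unreadable")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(.cohort_columns, names(tab))
  if (length(missing))
    an_stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
            "missing_column")
  tab <- tab[, .cohort_columns]
  age_num <- suppressWarnings(as.numeric(tab$age))
  if (any(is.na(age_num)))
    an_stop(sprintf("unparseable age value(s): %s",
                    paste(unique(tab$age[is.na(age_num)]), collapse = ", ")),
            "bad_age")
  if (any(age_num != floor(age_num))) {
    warning("fractional ages floored to integer years")
    age_num <- floor(age_num)
  }
  if (any(age_num < 0 | age_num > 120))
    an_stop("age out of range [0, 120]", "bad_age")
  tab$age <- as.integer(age_num)
  tab$sex <- normalize_sex(tab$sex)
  tab$subject_id <- as.character(tab$subject_id)
  dup <- tab$subject_id[duplicated(tab$subject_id)]
  if (length(dup))
    an_stop(sprintf("duplicate subject_id(s): %s",
                    paste(unique(dup), collapse = ", ")), "duplicate_id")
  tab
}

#' Write a cohort metadata table
#'
#' @param table a cohort `data.frame` as returned by [read_cohort_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(table, path) {
  missing <- setdiff(.cohort_columns, names(table))
  if (length(missing))
    an_stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
            "missing_column")
  utils::write.csv(table[, .cohort_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read a nested key-value configuration file
#'
#' YAML-formatted configuration selecting grid size, experiment parameters
#' and seeds. Returned as a nested list; callers pass relevant sections to
#' [experiment_config()] or [synthetic_cohort_spec()].
#'
#' @param path path to a YAML file.
#' @return nested list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) an_stop(sprintf("no such file: %s", path), "unreadable")
  yaml::read_yaml(path)
}
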