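# Cohort container, CSV round-trip and inclusion/exclusion filtering.
#
# A cohort is a plain data.frame (class "transplant_cohort") with one row per
# transplantation and a fixed, documented column set.  Missing cells stay NA
# (empty CSV cells); nothing is imputed.

#' Column dictionary of a transplant cohort
#'
#' @return character vector of the canonical column names, in file order.
#' @export
cohort_columns <- function() {
  c("subject_id", "country", "transplant_year", "recipient_age", "donor_age",
    "living_donor", "preemptive", "retransplant", "hla_mm", "hla_dr_mm",
    "primary_disease", "multi_organ", "in_europe", "follow_up_months",
    "graft_loss", "death_with_function")
}

#' Primary-disease categories
#'
#' The eight categories used for the underlying cause of kidney failure.
#' CAKUT (congenital anomalies of the kidney and urinary tract) is the
#' reference level in all models.
#'
#' @return character vector of the eight category labels.
#' @export
disease_levels <- function() {
  c("CAKUT", "ciliopathy", "glomerulopathy", "tubulopathy",
    "microvascular thrombopathy", "hereditary nephropathy",
    "metabolic nephropathy", "other")
}

#' Default pre-transplant predictor set
#'
#' @return character vector of covariate column names entering the hazard
#'   model by default.
#' @export
model_covariates <- function() {
  c("recipient_age", "donor_age", "living_donor", "preemptive",
    "retransplant", "hla_mm", "hla_dr_mm", "primary_disease")
}

cohort_col_types <- function() {
  c(subject_id = "character", country = "character",
    transplant_year = "integer", recipient_age = "numeric",
    donor_age = "numeric", living_donor = "logical", preemptive = "logical",
    retransplant = "logical", hla_mm = "integer", hla_dr_mm = "integer",
    primary_disease = "character", multi_organ = "logical",
    in_europe = "logical", follow_up_months = "integer",
    graft_loss = "logical", death_with_function = "logical")
}

#' Construct a transplant cohort from a data frame
#'
#' Validates the column set, types and record invariants (unique subject ids,
#' follow-up of at least one month, graft loss and death with functioning
#' graft mutually exclusive).
#'
#' @param df data.frame with the columns of [cohort_columns()].
#' @param source optional provenance label (e.g. a file path).
#' @param filter_log optional data.frame of prior exclusions.
#' @return a `transplant_cohort` (a data.frame).
#' @export
new_cohort <- function(df, source = NA_character_, filter_log = NULL) {
  cols <- cohort_columns()
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, cols, drop = FALSE]
  types <- cohort_col_types()
  for (cl in cols) {
    df[[cl]] <- switch(types[[cl]],
      character = as.character(df[[cl]]),
      integer = as.integer(df[[cl]]),
      numeric = as.numeric(df[[cl]]),
      logical = as.logical(df[[cl]]))
  }
  if (anyDuplicated(df$subject_id[!is.na(df$subject_id)])) {
    stop("subject_id values must be unique")
  }
  bad_fu <- !is.na(df$follow_up_months) & df$follow_up_months < 1L
  if (any(bad_fu)) {
    stop("follow_up_months must be >= 1 (rows: ",
         paste(head(which(bad_fu)), collapse = ", "), ")")
  }
  both <- !is.na(df$graft_loss) & !is.na(df$death_with_function) &
    df$graft_loss & df$death_with_function
  if (any(both)) {
    stop("graft_loss and death_with_function cannot both be TRUE (rows: ",
         paste(head(which(both)), collapse = ", "), ")")
  }
  bad_dis <- !is.na(df$primary_disease) &
    !(df$primary_disease %in% disease_levels())
  if (any(bad_dis)) {
    stop("unknown primary_disease label(s): ",
         paste(unique(df$primary_disease[bad_dis]), collapse = ", "))
  }
  neg_age <- !is.na(df$recipient_age) & df$recipient_age < 0
  if (any(neg_age)) stop("recipient_age must be non-negative")
  structure(df,
            source = source,
            filter_log = filter_log,
            class = c("transplant_cohort", "data.frame"))
}

#' Read a cohort CSV
#'
#' Reads a registry-style cohort file (comma-separated, UTF-8, header row,
#' decimal point).  Empty cells become NA; a non-empty cell that cannot be
#' parsed under the column's declared type is a parse error naming the file
#' line.  Unknown disease labels are rejected.
#'
#' @param path path to a CSV file with the columns of [cohort_columns()].
#' @return a `transplant_cohort`.
#' @export
read_cohort <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = character(), fileEncoding = "UTF-8")
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols)) {
    stop("file ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  types <- cohort_col_types()
  out <- raw
  for (cl in cohort_columns()) {
    x <- raw[[cl]]
    x[x == ""] <- NA_character_
    conv <- switch(types[[cl]],
      character = x,
      integer = suppressWarnings(as.integer(x)),
      numeric = suppressWarnings(as.numeric(x)),
      logical = parse_logical(x))
    bad <- !is.na(x) & is.na(conv)
    if (any(bad)) {
      stop(sprintf("parse error in %s at line %d, column '%s': %s",
                   path, which(bad)[1L] + 1L, cl, x[which(bad)[1L]]))
    }
    out[[cl]] <- conv
  }
  new_cohort(out, source = path)
}

parse_logical <- function(x) {
  low <- tolower(x)
  out <- rep(NA, length(x))
  out[low %in% c("true", "t", "1")] <- TRUE
  out[low %in% c("false", "f", "0")] <- FALSE
  out
}

#' Write a cohort CSV
#'
#' Fixed column order, UTF-8, comma separator, decimal point, empty cells for
#' missing values; round-trips through [read_cohort()].
#'
#' @param cohort a `transplant_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)[, cohort_columns(), drop = FALSE]
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write cohort to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Apply the inclusion and exclusion rules
#'
#' Retains transplantations performed 2005-2021 in recipients under 19 years
#' of age, excluding multi-organ transplantations, transplantations outside
#' Europe, and records with any missing model covariate or outcome field
#' (complete-case rule).  Each excluded record is assigned the first matching
#' reason in the fixed order `year`, `age`, `multi_organ`, `outside_europe`,
#' `incomplete`; a record whose eligibility for an earlier rule cannot be
#' judged because the field is missing falls through to `incomplete`.
#'
#' The filter is idempotent: re-applying it to its own output excludes
#' nothing.
#'
#' @param cohort a `transplant_cohort`.
#' @param year_range inclusive calendar-year window, default `c(2005, 2021)`.
#' @param max_age exclusive recipient-age bound in years ("under 19").
#' @return list with elements `cohort` (retained records, with the log
#'   attached as attribute `filter_log`) and `log` (data.frame of exclusion
#'   reason counts, in rule order).
#' @export
apply_inclusion <- function(cohort, year_range = c(2005L, 2021L),
                            max_age = 19) {
  df <- as.data.frame(cohort)
  n <- nrow(df)
  required <- c("country", "transplant_year", "multi_organ", "in_europe",
                model_covariates(), "follow_up_months", "graft_loss",
                "death_with_function")
  reason <- rep(NA_character_, n)
  known <- function(x) !is.na(x)

  bad_year <- known(df$transplant_year) &
    (df$transplant_year < year_range[1L] | df$transplant_year > year_range[2L])
  bad_age <- known(df$recipient_age) & df$recipient_age >= max_age
  bad_multi <- known(df$multi_organ) & df$multi_organ
  bad_europe <- known(df$in_europe) & !df$in_europe
  incomplete <- !complete.cases(df[, required, drop = FALSE])

  reason[is.na(reason) & bad_year] <- "year"
  reason[is.na(reason) & bad_age] <- "age"
  reason[is.na(reason) & bad_multi] <- "multi_organ"
  reason[is.na(reason) & bad_europe] <- "outside_europe"
  reason[is.na(reason) & incomplete] <- "incomplete"

  reasons <- c("year", "age", "multi_organ", "outside_europe", "incomplete")
  log <- data.frame(reason = reasons,
                    n_excluded = vapply(reasons,
                                        function(r) sum(reason == r, na.rm = TRUE),
                                        integer(1L)),
                    row.names = NULL, stringsAsFactors = FALSE)
  keep <- is.na(reason)
  stopifnot(sum(keep) + sum(log$n_excluded) == n)
  retained <- new_cohort(df[keep, , drop = FALSE],
                         source = attr(cohort, "source"),
                         filter_log = log)
  rownames(retained) <- NULL
  list(cohort = retained, log = log)
}
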