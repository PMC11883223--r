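# Person-period expansion: one row per subject per at-risk month.

#' Expand a cohort into a person-period table
#'
#' Each subject contributes rows for months 1..`follow_up_months`;
#' `event` is 1 in the final row if and only if the graft was lost.  Death
#' with a functioning graft and administrative end of follow-up are
#' censoring (final row has `event = 0`).  A `weight` column is carried
#' through (all 1 unless the cohort already has one, e.g. from
#' [country_weights()]).
#'
#' @param cohort a `transplant_cohort` (normally after [apply_inclusion()]).
#' @param spec optional [spline_spec()]; when supplied, the natural-spline
#'   time basis columns are attached.
#' @return data.frame with columns `subject_id`, `month`, `event`, the
#'   covariates, `country`, `weight`, and (optionally) the basis columns.
#' @export
expand_person_period <- function(cohort, spec = NULL) {
  df <- as.data.frame(cohort)
  fu <- df$follow_up_months
  if (anyNA(fu) || any(fu < 1L)) {
    stop("follow_up_months must be present and >= 1 for every record")
  }
  idx <- rep.int(seq_len(nrow(df)), fu)
  month <- sequence(fu)
  keep <- c("subject_id", "country", model_covariates())
  pp <- df[idx, keep, drop = FALSE]
  pp$month <- month
  last <- month == fu[idx]
  pp$event <- as.integer(last & df$graft_loss[idx])
  pp$weight <- if (!is.null(df$weight)) df$weight[idx] else 1
  rownames(pp) <- NULL
  if (!is.null(spec)) pp <- add_spline_basis(pp, spec)
  pp
}

#' Attach (or refresh) the spline time-basis columns
#'
#' @param pp a person-period table with a `month` column.
#' @param spec a [spline_spec()].
#' @return `pp` with columns `time_ns1..time_ns<k>` replaced.
#' @export
add_spline_basis <- function(pp, spec) {
  b <- spline_design(pp$month, spec)
  pp[colnames(b)] <- as.data.frame(b)
  attr(pp, "spline_spec") <- spec
  pp
}
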