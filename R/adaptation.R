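# Model updating for new populations: inverse-size country weighting,
# country dummy variables, full coefficient re-estimation, and the pooled
# international model.

#' Inverse-size country weights
#'
#' `weight_c = N_total / (K * n_c)` for K countries, so that every country
#' contributes the same total weight and the overall effective sample size is
#' preserved (`sum(weight_c * n_c) = N_total`).  Equal cohort sizes give all
#' weights 1.
#'
#' @param cohort a `transplant_cohort` with a `country` column.
#' @return a `weight_scheme`: named numeric vector of per-country weights
#'   with the per-country sizes as attribute `n`.
#' @export
country_weights <- function(cohort) {
  df <- as.data.frame(cohort)
  if (!nrow(df)) stop("cohort is empty")
  if (anyNA(df$country)) stop("country labels must be complete")
  n_c <- table(df$country)
  K <- length(n_c)
  w <- as.numeric(nrow(df)) / (K * as.numeric(n_c))
  structure(setNames(w, names(n_c)), n = as.integer(n_c),
            class = "weight_scheme")
}

#' Attach subject weights from a weight scheme
#'
#' @param cohort a `transplant_cohort`.
#' @param scheme a [country_weights()] scheme (default computed from the
#'   cohort itself).
#' @return the cohort with a `weight` column; the weight is replicated
#'   across a subject's person-period rows by [expand_person_period()].
#' @export
add_weights <- function(cohort, scheme = country_weights(cohort)) {
  df <- as.data.frame(cohort)
  unknown <- setdiff(unique(df$country), names(scheme))
  if (length(unknown)) {
    stop("no weight for country: ", paste(unknown, collapse = ", "))
  }
  df$weight <- unname(scheme[df$country])
  out <- new_cohort(df[, cohort_columns(), drop = FALSE],
                    source = attr(cohort, "source"))
  out$weight <- df$weight
  out
}

#' Add country dummy variables to a model specification
#'
#' One-hot country indicators with the largest cohort as reference.  A
#' single-country cohort leaves the specification unchanged with a warning.
#'
#' @param spec a [hazard_spec()].
#' @param cohort the cohort whose countries define the encoding.
#' @return updated `hazard_spec`.
#' @export
add_country_dummies <- function(spec, cohort) {
  stopifnot(inherits(spec, "hazard_spec"))
  counts <- table(as.data.frame(cohort)$country)
  if (length(counts) < 2L) {
    warning("single-country cohort: country dummies not added")
    return(spec)
  }
  spec$country_dummies <- TRUE
  spec$country_ref <- spec$country_ref %||% names(counts)[which.max(counts)]
  spec
}

#' Re-estimate the model on a new cohort
#'
#' Full model updating with the predictor set held fixed: a fresh 80/20
#' derivation/validation split, knot placement on the new derivation
#' person-period months, a maximum-likelihood refit of all coefficients, and
#' an internal validation report.  The input specification is not modified.
#'
#' @param cohort a filtered `transplant_cohort`.
#' @param spec a [hazard_spec()] (default: standard predictors, no dummies).
#' @param fraction derivation fraction (default 0.8).
#' @param seed integer seed driving the split and bootstrap.
#' @param years,horizon,groups,n_boot forwarded to [internal_validate()].
#' @param label report label.
#' @return list `(model, report, derivation, validation)`.
#' @export
reestimate <- function(cohort, spec = hazard_spec(), fraction = 0.8,
                       seed = 1L, years = 1:15, horizon = 60L, groups = 10L,
                       n_boot = 2000L, label = "internal") {
  halves <- split_cohort(cohort, fraction, seed = derive_seed(seed, 1L))
  pp <- expand_person_period(halves$derivation)
  knots <- place_knots(pp$month)
  pp <- add_spline_basis(pp, knots)
  model <- fit_hazard(pp, spec)
  report <- internal_validate(model, halves$validation, years = years,
                              horizon = horizon, groups = groups,
                              n_boot = n_boot,
                              seed = derive_seed(seed, 2L), label = label)
  list(model = model, report = report,
       derivation = halves$derivation, validation = halves$validation)
}

#' Pooled international model
#'
#' Composes inverse-size country weighting (computed on the derivation
#' cohort), country dummy variables (reference = largest cohort) and the
#' standard develop-and-validate workflow on a multi-country cohort; the
#' weights multiply the person-period log-likelihood.
#'
#' @inheritParams reestimate
#' @param weighted set FALSE to force all weights to 1 (plain pooled fit).
#' @return list `(model, report, weights, derivation, validation)`.
#' @export
build_international_model <- function(cohort, spec = hazard_spec(),
                                      fraction = 0.8, seed = 1L,
                                      years = 1:15, horizon = 60L,
                                      groups = 10L, n_boot = 2000L,
                                      weighted = TRUE,
                                      label = "international") {
  df <- as.data.frame(cohort)
  if (length(unique(df$country)) < 2L) {
    stop("international model needs at least 2 countries")
  }
  halves <- split_cohort(cohort, fraction, seed = derive_seed(seed, 1L))
  scheme <- country_weights(halves$derivation)
  if (!weighted) scheme[] <- 1
  der <- add_weights(halves$derivation, scheme)
  spec <- add_country_dummies(spec, der)
  pp <- expand_person_period(der)
  knots <- place_knots(pp$month)
  pp <- add_spline_basis(pp, knots)
  model <- fit_hazard(pp, spec)
  report <- internal_validate(model, halves$validation, years = years,
                              horizon = horizon, groups = groups,
                              n_boot = n_boot,
                              seed = derive_seed(seed, 2L), label = label)
  list(model = model, report = report, weights = scheme,
       derivation = halves$derivation, validation = halves$validation)
}
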