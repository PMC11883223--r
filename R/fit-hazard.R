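# Discrete-time logistic hazard model: design encoding, Newton/IRLS maximum
# likelihood with optional ridge penalty and person-period weights, and
# monthly survival prediction.

#' Hazard model specification
#'
#' Selects the covariates and structural terms of the discrete-time logistic
#' hazard model.  Categorical covariates are one-hot encoded against fixed
#' reference levels: `primary_disease` against CAKUT, `country` (when dummy
#' variables are requested) against the largest cohort.
#'
#' @param covariates character vector of covariate columns; the default is
#'   the standard pre-transplant predictor set of [model_covariates()].
#' @param country_dummies add one-hot country indicators?
#' @param country_ref reference country; default the largest cohort at fit
#'   time.
#' @param disease_ref reference disease category.
#' @param penalty ridge weight on all non-intercept coefficients (0 = plain
#'   maximum likelihood; a tiny value such as 1e-6 stabilises separable toy
#'   data).
#' @return a `hazard_spec`.
#' @export
hazard_spec <- function(covariates = model_covariates(),
                        country_dummies = FALSE, country_ref = NULL,
                        disease_ref = "CAKUT", penalty = 0) {
  if (penalty < 0) stop("penalty must be >= 0")
  structure(list(covariates = covariates,
                 country_dummies = isTRUE(country_dummies),
                 country_ref = country_ref,
                 disease_ref = disease_ref,
                 penalty = penalty),
            class = "hazard_spec")
}

# Freeze factor encodings from the fitting data so prediction is reproducible
build_encoding <- function(pp, spec) {
  enc <- list(covariates = spec$covariates,
              disease_ref = spec$disease_ref,
              disease_levels = disease_levels(),
              country_levels = NULL, country_ref = NULL)
  if (spec$country_dummies) {
    counts <- table(pp$country[!duplicated(pp$subject_id)])
    ref <- spec$country_ref %||% names(counts)[which.max(counts)]
    if (!ref %in% names(counts)) {
      stop("country_ref '", ref, "' not present in the data")
    }
    enc$country_levels <- sort(names(counts))
    enc$country_ref <- ref
  }
  enc
}

# Design matrix (intercept first, then covariates, country dummies, spline)
design_matrix <- function(df, enc, spline_names) {
  n <- nrow(df)
  cols <- list(`(Intercept)` = rep(1, n))
  for (cv in enc$covariates) {
    if (cv == "primary_disease") {
      dis <- as.character(df$primary_disease)
      bad <- !(dis %in% enc$disease_levels)
      if (any(bad)) {
        stop("unknown primary_disease level(s): ",
             paste(unique(dis[bad]), collapse = ", "))
      }
      for (lv in setdiff(enc$disease_levels, enc$disease_ref)) {
        cols[[paste0("primary_disease=", lv)]] <- as.numeric(dis == lv)
      }
    } else {
      x <- df[[cv]]
      if (is.null(x)) stop("covariate '", cv, "' not found")
      cols[[cv]] <- as.numeric(x)
    }
  }
  if (!is.null(enc$country_levels)) {
    ctry <- as.character(df$country)
    bad <- !(ctry %in% enc$country_levels)
    if (any(bad)) {
      stop("unmappable country level(s): ",
           paste(unique(ctry[bad]), collapse = ", "))
    }
    for (lv in setdiff(enc$country_levels, enc$country_ref)) {
      cols[[paste0("country=", lv)]] <- as.numeric(ctry == lv)
    }
  }
  for (sn in spline_names) {
    x <- df[[sn]]
    if (is.null(x)) stop("spline column '", sn, "' missing; run add_spline_basis()")
    cols[[sn]] <- as.numeric(x)
  }
  do.call(cbind, cols)
}

# Newton/IRLS maximiser of the (weighted, optionally ridge-penalised)
# Bernoulli log-likelihood.  Convergence: relative penalised log-likelihood
# change < tol.  Step-halving guards against overshoot.
fit_irls <- function(X, y, w, penalty = 0, max_iter = 100L, tol = 1e-10) {
  p <- ncol(X)
  pen <- rep(penalty, p)
  pen[1L] <- 0  # intercept unpenalised
  beta <- numeric(p)
  beta[1L] <- qlogis(clamp_prob(sum(w * y) / sum(w)))
  pll <- function(b) {
    mu <- clamp_prob(plogis(drop(X %*% b)))
    sum(w * (y * log(mu) + (1 - y) * log(1 - mu))) - 0.5 * sum(pen * b^2)
  }
  ll_old <- pll(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- clamp_prob(plogis(eta))
    grad <- drop(crossprod(X, w * (y - mu))) - pen * beta
    wv <- w * mu * (1 - mu)
    H <- crossprod(X, X * wv)
    diag(H) <- diag(H) + pen + 1e-12
    step <- tryCatch(solve(H, grad), error = function(e)
      stop("singular information matrix; consider a ridge penalty"))
    # step-halving until the penalised log-likelihood does not decrease
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- pll(cand)
      if (ll_new >= ll_old - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    beta <- cand
    if (abs(ll_new - ll_old) < tol * (abs(ll_new) + 1e-8)) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  # complete separation: coefficients diverge while the likelihood is
  # driven to a perfect fit
  if (penalty == 0 && max(abs(beta)) > 15 &&
      (!converged || ll_old / length(y) > -1e-5)) {
    stop("complete separation detected (diverging coefficients); ",
         "refit with penalty > 0")
  }
  mu <- clamp_prob(plogis(drop(X %*% beta)))
  list(coef = setNames(drop(beta), colnames(X)),
       log_likelihood = sum(w * (y * log(mu) + (1 - y) * log(1 - mu))),
       converged = converged, iterations = it)
}

#' Fit the discrete-time logistic hazard model
#'
#' Maximises the weighted Bernoulli log-likelihood
#' `sum w_i [y_i log h_i + (1 - y_i) log(1 - h_i)]` with
#' `h_i = plogis(eta_i)` over the person-period rows by Newton iteration
#' (relative log-likelihood tolerance 1e-10, at most 100 iterations).
#'
#' @param pp person-period table from [expand_person_period()], with spline
#'   basis columns attached.
#' @param spec a [hazard_spec()].
#' @param spline a [spline_spec()]; defaults to the one attached to `pp`.
#' @param weights optional row weights; default the `weight` column (else 1).
#' @return a `hazard_fit` with elements `intercept`, `beta` (named covariate
#'   coefficients), `gamma` (spline coefficients), `country` (dummy
#'   coefficients or NULL), `spline_spec`, `encoding`, `log_likelihood`,
#'   `converged`, `n_obs`, `n_events`.
#' @export
fit_hazard <- function(pp, spec = hazard_spec(), spline = NULL,
                       weights = NULL) {
  stopifnot(inherits(spec, "hazard_spec"))
  spline <- spline %||% attr(pp, "spline_spec")
  spline_names <- if (is.null(spline)) character() else spline_colnames(spline)
  if (!nrow(pp)) stop("person-period table is empty")
  y <- as.numeric(pp$event)
  if (sum(y) == 0) stop("no events in the person-period table; cannot fit")
  w <- weights %||% pp$weight %||% rep(1, nrow(pp))
  if (any(w <= 0)) stop("weights must be positive")
  enc <- build_encoding(pp, spec)
  X <- design_matrix(pp, enc, spline_names)
  fit <- fit_irls(X, y, w, penalty = spec$penalty)

  nms <- names(fit$coef)
  is_spline <- nms %in% spline_names
  is_country <- startsWith(nms, "country=")
  is_int <- nms == "(Intercept)"
  structure(list(
    intercept = unname(fit$coef[is_int]),
    beta = fit$coef[!is_int & !is_spline & !is_country],
    gamma = fit$coef[is_spline],
    country = if (any(is_country)) fit$coef[is_country] else NULL,
    spline_spec = spline,
    encoding = enc,
    penalty = spec$penalty,
    log_likelihood = fit$log_likelihood,
    converged = fit$converged,
    iterations = fit$iterations,
    n_obs = nrow(pp),
    n_events = sum(y),
    n_subjects = length(unique(pp$subject_id))),
    class = "hazard_fit")
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat("discrete-time logistic hazard model\n")
  cat(sprintf("  %d person-months, %d events, %d subjects\n",
              x$n_obs, x$n_events, x$n_subjects))
  cat(sprintf("  log-likelihood %.4f (%sconverged, %d iterations)\n",
              x$log_likelihood, if (x$converged) "" else "NOT ",
              x$iterations))
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.hazard_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta, object$country,
    object$gamma)
}

model_linpred <- function(model, records, months = NULL) {
  df <- as.data.frame(records)
  spline_names <- if (is.null(model$spline_spec)) character()
                  else spline_colnames(model$spline_spec)
  if (length(spline_names) && !is.null(months)) {
    # covariate part only; the month part is added by the caller
    spline_names <- character()
  }
  X <- design_matrix(df, model$encoding, spline_names)
  drop(X %*% c(model$intercept, model$beta, model$country,
               if (length(spline_names)) model$gamma))
}

#' Predicted monthly hazard for one covariate profile
#'
#' @param model a converged `hazard_fit`.
#' @param record one-row data.frame (or list) with the model covariates.
#' @param month vector of months (>= 1).
#' @return hazard probabilities in (0, 1), one per month.
#' @export
predict_hazard <- function(model, record, month) {
  stopifnot(inherits(model, "hazard_fit"))
  if (!isTRUE(model$converged)) {
    stop("model did not converge; refusing to predict")
  }
  month <- as.numeric(month)
  if (any(month < 1)) stop("month must be >= 1")
  record <- as.data.frame(record, stringsAsFactors = FALSE)
  if (nrow(record) != 1L) stop("record must be a single covariate profile")
  lp_cov <- model_linpred(model, record, months = month)
  lp_time <- if (length(model$gamma)) {
    drop(spline_design(month, model$spline_spec) %*% model$gamma)
  } else rep(0, length(month))
  clamp_prob(plogis(lp_cov + lp_time))
}

#' Predicted monthly graft-survival curve
#'
#' `S(t) = prod_{m=1..t} (1 - h(m))`, with `h` the predicted monthly hazard.
#'
#' @param model a converged `hazard_fit`.
#' @param record one-row covariate profile.
#' @param horizon months (>= 1).
#' @param label optional curve label.
#' @return a `survival_curve`: list with `month`, `hazard`, `survival`.
#' @export
predict_survival <- function(model, record, horizon, label = NULL) {
  if (horizon < 1) stop("horizon must be >= 1")
  months <- seq_len(horizon)
  h <- predict_hazard(model, record, months)
  structure(list(month = months, hazard = h, survival = cumprod(1 - h),
                 label = label),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("monthly graft-survival curve",
      if (!is.null(x$label)) paste0("[", x$label, "]"), "\n")
  show <- unique(pmin(c(12, 60, 120, max(x$month)), max(x$month)))
  print(data.frame(month = show, survival = round(x$survival[show], 4)))
  invisible(x)
}

#' Compare donor scenarios for one recipient
#'
#' Applies donor-side overrides (`donor_age`, `living_donor`, `hla_mm`,
#' `hla_dr_mm`, `preemptive`) to a baseline record and returns one labelled
#' survival curve per scenario; overriding a recipient-side field is an
#' error.
#'
#' @param model a converged `hazard_fit`.
#' @param record baseline one-row covariate profile.
#' @param donor_variants named list of named override lists.
#' @param horizon months.
#' @return named list of `survival_curve`s.
#' @export
compare_scenarios <- function(model, record, donor_variants, horizon) {
  allowed <- c("donor_age", "living_donor", "hla_mm", "hla_dr_mm",
               "preemptive")
  record <- as.data.frame(record, stringsAsFactors = FALSE)
  out <- vector("list", length(donor_variants))
  labels <- names(donor_variants) %||% paste0("variant", seq_along(donor_variants))
  for (i in seq_along(donor_variants)) {
    ov <- donor_variants[[i]]
    bad <- setdiff(names(ov), allowed)
    if (length(bad)) {
      stop("only donor-side fields may be overridden; offending: ",
           paste(bad, collapse = ", "))
    }
    rec <- record
    rec[names(ov)] <- ov
    out[[i]] <- predict_survival(model, rec, horizon, label = labels[i])
  }
  names(out) <- labels
  out
}

#' Serialise a fitted hazard model to JSON
#'
#' Coefficients, spline specification, encoding map and fit metadata; the
#' output is byte-stable given identical input.
#'
#' @param model a `hazard_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hazard_model <- function(model, path) {
  obj <- list(
    type = "pktsurv_hazard_fit",
    intercept = model$intercept,
    beta = as.list(model$beta),
    gamma = as.list(model$gamma),
    country = if (is.null(model$country)) NULL else as.list(model$country),
    spline_spec = list(interior_knots = model$spline_spec$interior_knots,
                       boundary_knots = model$spline_spec$boundary_knots),
    encoding = model$encoding,
    penalty = model$penalty,
    log_likelihood = model$log_likelihood,
    converged = model$converged,
    iterations = model$iterations,
    n_obs = model$n_obs, n_events = model$n_events,
    n_subjects = model$n_subjects)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a hazard model serialised by [write_hazard_model()]
#'
#' @param path JSON file path.
#' @return a `hazard_fit`.
#' @export
read_hazard_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "pktsurv_hazard_fit")) {
    stop(path, " is not a serialised hazard model")
  }
  spec <- spline_spec(obj$spline_spec$interior_knots,
                      obj$spline_spec$boundary_knots)
  enc <- obj$encoding
  enc$covariates <- as.character(enc$covariates)
  structure(list(
    intercept = obj$intercept,
    beta = unlist(obj$beta),
    gamma = unlist(obj$gamma),
    country = if (length(obj$country)) unlist(obj$country) else NULL,
    spline_spec = spec,
    encoding = enc,
    penalty = obj$penalty,
    log_likelihood = obj$log_likelihood,
    converged = obj$converged,
    iterations = obj$iterations,
    n_obs = obj$n_obs, n_events = obj$n_events,
    n_subjects = obj$n_subjects),
    class = "hazard_fit")
}
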