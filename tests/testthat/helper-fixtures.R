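# Shared fixtures: tiny cohorts, simple truth models and hand-made fitted
# models, all built in code.

toy_cohort <- function(n = 5,
                       follow_up = rep(12L, n),
                       graft_loss = rep(FALSE, n),
                       death_with_function = rep(FALSE, n),
                       country = rep("NL", n),
                       transplant_year = rep(2010L, n),
                       recipient_age = rep(10, n),
                       donor_age = rep(35, n),
                       living_donor = rep(FALSE, n),
                       preemptive = rep(FALSE, n),
                       retransplant = rep(FALSE, n),
                       hla_mm = rep(3L, n),
                       hla_dr_mm = rep(1L, n),
                       primary_disease = rep("CAKUT", n),
                       multi_organ = rep(FALSE, n),
                       in_europe = rep(TRUE, n),
                       subject_id = sprintf("S%03d", seq_len(n))) {
  new_cohort(data.frame(
    subject_id = subject_id, country = country,
    transplant_year = transplant_year, recipient_age = recipient_age,
    donor_age = donor_age, living_donor = living_donor,
    preemptive = preemptive, retransplant = retransplant,
    hla_mm = hla_mm, hla_dr_mm = hla_dr_mm,
    primary_disease = primary_disease, multi_organ = multi_organ,
    in_europe = in_europe, follow_up_months = follow_up,
    graft_loss = graft_loss, death_with_function = death_with_function,
    stringsAsFactors = FALSE))
}

# constant-hazard truth: hazard plogis(intercept) in every month
flat_truth <- function(intercept, admin_horizon = 60L, dropout_rate = 0,
                       death_rate = 0) {
  truth_model(intercept = intercept,
              beta = list(),
              gamma = rep(0, 5),
              spline_spec = spline_spec(c(5, 15, 30, 45), c(1, 60)),
              dropout_rate = dropout_rate, death_rate = death_rate,
              admin_horizon = admin_horizon, study_end_year = NULL)
}

# hand-made fitted model with known coefficients (no data behind it)
make_model <- function(intercept, beta = numeric(0), gamma = NULL,
                       spline = NULL) {
  structure(list(
    intercept = intercept,
    beta = beta,
    gamma = if (is.null(gamma)) numeric(0) else
      setNames(gamma, paste0("time_ns", seq_along(gamma))),
    country = NULL,
    spline_spec = spline,
    encoding = list(covariates = names(beta), disease_ref = "CAKUT",
                    disease_levels = disease_levels(),
                    country_levels = NULL, country_ref = NULL),
    penalty = 0, log_likelihood = NA_real_, converged = TRUE,
    iterations = 0L, n_obs = 0L, n_events = 0L, n_subjects = 0L),
    class = "hazard_fit")
}

# cohort payload stripped of provenance attributes, for equality checks
cohort_data <- function(x) {
  df <- as.data.frame(x)
  attr(df, "source") <- NULL
  attr(df, "filter_log") <- NULL
  class(df) <- "data.frame"
  rownames(df) <- NULL
  df
}

# exhaustive concordance count over all case-control pairs (ties = 1/2)
brute_force_auc <- function(risk, is_case) {
  cases <- risk[is_case]
  controls <- risk[!is_case]
  tot <- 0
  for (rc in cases) {
    tot <- tot + sum(rc > controls) + 0.5 * sum(rc == controls)
  }
  tot / (length(cases) * length(controls))
}

# coarse-to-fine exhaustive grid maximiser of the Bernoulli log-likelihood
# for an intercept + one binary covariate person-period layout
grid_mle_1cov <- function(n11, n10, n01, n00) {
  # n11 events with x=1, n10 non-events with x=1, n01/n00 likewise for x=0
  ll <- function(a, b) {
    p1 <- plogis(a + b); p0 <- plogis(a)
    n11 * log(p1) + n10 * log(1 - p1) + n01 * log(p0) + n00 * log(1 - p0)
  }
  best <- c(0, 0)
  for (step in c(0.05, 0.001)) {
    as <- seq(best[1] - ifelse(step == 0.05, 5, 0.06),
              best[1] + ifelse(step == 0.05, 5, 0.06), by = step)
    bs <- seq(best[2] - ifelse(step == 0.05, 5, 0.06),
              best[2] + ifelse(step == 0.05, 5, 0.06), by = step)
    g <- outer(as, bs, ll)
    ix <- arrayInd(which.max(g), dim(g))
    best <- c(as[ix[1]], bs[ix[2]])
  }
  best
}
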