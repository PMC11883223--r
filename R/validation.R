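# Discrimination and calibration assessment: derivation/validation split,
# yearly time-dependent ROC-AUC (cumulative cases / dynamic controls),
# decile calibration tables, Hosmer-Lemeshow test, and composed
# internal/external validation reports.

#' Random derivation/validation split
#'
#' Simple random split at the subject level: `ceiling(fraction * n)` records
#' form the derivation cohort, the remainder the validation cohort.
#'
#' @param cohort a `transplant_cohort` with at least 10 records.
#' @param fraction derivation fraction, strictly inside (0, 1); default 0.8.
#' @param seed integer seed (split is deterministic given it).
#' @return list with `derivation` and `validation` cohorts.
#' @export
split_cohort <- function(cohort, fraction = 0.8, seed = NULL) {
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be strictly between 0 and 1")
  }
  df <- as.data.frame(cohort)
  n <- nrow(df)
  if (n < 10L) stop("cohort must have at least 10 records to split")
  if (!is.null(seed)) set.seed(seed)
  n_der <- ceiling(fraction * n)
  idx <- sample.int(n, n_der)
  der <- df[sort(idx), , drop = FALSE]
  val <- df[-sort(idx), , drop = FALSE]
  rownames(der) <- rownames(val) <- NULL
  list(derivation = new_cohort(der, source = attr(cohort, "source")),
       validation = new_cohort(val, source = attr(cohort, "source")))
}

# midrank concordance of risk over all case-control pairs (ties count 1/2)
auc_concordance <- function(risk, is_case) {
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(risk)  # midranks
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Time-dependent ROC-AUC at a yearly anniversary
#'
#' Cumulative-cases / dynamic-controls definition at `t = 12 * year` months:
#' cases lost their graft at or before `t`; controls were followed beyond `t`
#' without graft loss (death with functioning graft counts as a non-event,
#' so such subjects are controls when followed past `t`); subjects censored
#' before `t` without an event are excluded.  The AUC is the concordance of
#' the risk score (1 - predicted survival at `t`) over all case-control
#' pairs, ties counting one half.  The 95% CI is a subject-level percentile
#' bootstrap.
#'
#' @param pred_survival per-subject predicted survival probability at `t`.
#' @param follow_up per-subject follow-up in months.
#' @param event per-subject graft-loss indicator.
#' @param year anniversary (t = 12 * year months).
#' @param n_boot bootstrap resamples for the CI (default 2000; 0 skips the
#'   CI).
#' @param seed integer seed for the bootstrap.
#' @return list `(year, auc, ci_lower, ci_upper, n_cases, n_controls)`; all
#'   NA (except counts) when there is no case or no control at `t`.
#' @export
year_auc <- function(pred_survival, follow_up, event, year,
                     n_boot = 2000L, seed = NULL) {
  t_m <- 12 * year
  event <- as.logical(event)
  is_case <- event & follow_up <= t_m
  is_control <- follow_up > t_m
  eligible <- is_case | is_control
  n1 <- sum(is_case)
  n0 <- sum(is_control)
  if (n1 == 0L || n0 == 0L) {
    return(list(year = year, auc = NA_real_, ci_lower = NA_real_,
                ci_upper = NA_real_, n_cases = n1, n_controls = n0))
  }
  risk <- 1 - pred_survival
  auc <- auc_concordance(risk[eligible], is_case[eligible])
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    el_risk <- risk[eligible]
    el_case <- is_case[eligible]
    m <- length(el_risk)
    boots <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      ix <- sample.int(m, m, replace = TRUE)
      boots[b] <- auc_concordance(el_risk[ix], el_case[ix])
    }
    boots <- boots[!is.na(boots)]
    if (length(boots)) {
      ci <- unname(quantile(boots, c(0.025, 0.975), type = 7))
      # a percentile interval can, in tiny samples, just miss the point
      # estimate; report an interval that contains it
      ci[1L] <- min(ci[1L], auc)
      ci[2L] <- max(ci[2L], auc)
    }
  }
  list(year = year, auc = auc, ci_lower = ci[1L], ci_upper = ci[2L],
       n_cases = n1, n_controls = n0)
}

#' Decile calibration table
#'
#' Equal-frequency bins by rank of predicted survival (bin sizes differ by at
#' most one; ties broken by stable subject order).  Per bin: mean predicted
#' survival and observed survival by Kaplan-Meier within the bin at the
#' horizon.
#'
#' @param pred_survival per-subject predicted survival at `horizon`.
#' @param follow_up,event per-subject follow-up (months) and graft-loss flag.
#' @param groups number of bins (default 10); must not exceed `n`.
#' @param horizon months at which calibration is read.
#' @return data.frame `(bin, n, mean_predicted, observed)`.
#' @export
calibration_table <- function(pred_survival, follow_up, event, groups = 10L,
                              horizon) {
  n <- length(pred_survival)
  if (groups > n) stop("groups must not exceed the number of subjects")
  ord <- order(pred_survival, seq_len(n))  # stable in ties
  sizes <- rep(n %/% groups, groups)
  if (n %% groups) sizes[seq_len(n %% groups)] <- sizes[seq_len(n %% groups)] + 1L
  bin_of_sorted <- rep.int(seq_len(groups), sizes)
  bin <- integer(n)
  bin[ord] <- bin_of_sorted
  out <- data.frame(bin = seq_len(groups), n = sizes,
                    mean_predicted = NA_real_, observed = NA_real_)
  for (g in seq_len(groups)) {
    in_g <- bin == g
    out$mean_predicted[g] <- mean(pred_survival[in_g])
    out$observed[g] <- km_survival_at(follow_up[in_g], event[in_g], horizon)
  }
  out
}

# KM survival probability at a single time (product-limit; extends flat)
km_survival_at <- function(follow_up, event, time) {
  fit <- survival::survfit(survival::Surv(follow_up, as.integer(event)) ~ 1)
  s <- summary(fit, times = time, extend = TRUE)
  as.numeric(s$surv[1L])
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Subjects are grouped into equal-frequency bins by predicted event
#' probability; the statistic sums `(observed - expected)^2 / expected` over
#' groups and both outcome cells; df = groups - 2.  A group whose expected
#' event (or non-event) count is zero is merged with its neighbour, reducing
#' df; merges are recorded in the result.
#'
#' @param p predicted event probabilities.
#' @param y observed binary outcomes (0/1).
#' @param groups number of groups (default 10).
#' @return list `(statistic, df, p_value, table, n_merged)`.
#' @export
hosmer_lemeshow <- function(p, y, groups = 10L) {
  n <- length(p)
  if (n < groups) stop("need at least as many subjects as groups")
  y <- as.numeric(y)
  ord <- order(p, seq_len(n))
  sizes <- rep(n %/% groups, groups)
  if (n %% groups) sizes[seq_len(n %% groups)] <- sizes[seq_len(n %% groups)] + 1L
  g_sorted <- rep.int(seq_len(groups), sizes)
  gidx <- integer(n)
  gidx[ord] <- g_sorted
  tab <- data.frame(
    group = seq_len(groups),
    n = as.integer(sizes),
    observed = vapply(seq_len(groups), function(g) sum(y[gidx == g]), 0),
    expected = vapply(seq_len(groups), function(g) sum(p[gidx == g]), 0))
  # merge groups with a zero expected cell into the neighbour above
  n_merged <- 0L
  repeat {
    zero <- which(tab$expected <= 0 | (tab$n - tab$expected) <= 0)
    if (!length(zero) || nrow(tab) <= 1L) break
    g <- zero[1L]
    nb <- if (g < nrow(tab)) g + 1L else g - 1L
    tab$n[nb] <- tab$n[nb] + tab$n[g]
    tab$observed[nb] <- tab$observed[nb] + tab$observed[g]
    tab$expected[nb] <- tab$expected[nb] + tab$expected[g]
    tab <- tab[-g, , drop = FALSE]
    n_merged <- n_merged + 1L
  }
  rownames(tab) <- NULL
  stat <- sum((tab$observed - tab$expected)^2 / tab$expected +
              ((tab$n - tab$observed) - (tab$n - tab$expected))^2 /
                (tab$n - tab$expected))
  df <- nrow(tab) - 2L
  p_value <- if (df >= 1L) pchisq(stat, df, lower.tail = FALSE) else NA_real_
  list(statistic = stat, df = df, p_value = p_value, table = tab,
       n_merged = n_merged)
}

score_cohort <- function(model, cohort, months) {
  df <- as.data.frame(cohort)
  H <- max(months)
  lp_cov <- model_linpred(model, df, months = months)
  lp_time <- drop(spline_design(seq_len(H), model$spline_spec) %*% model$gamma)
  haz <- clamp_prob(plogis(outer(lp_cov, lp_time, "+")))
  S <- cumprod_rows(1 - haz)
  S[, months, drop = FALSE]
}

validate_cohort <- function(model, cohort, years, horizon, groups, n_boot,
                            seed, label) {
  if (!isTRUE(model$converged)) stop("model did not converge")
  df <- as.data.frame(cohort)
  months_needed <- sort(unique(c(12 * years, horizon)))
  S <- score_cohort(model, cohort, months_needed)
  colnames(S) <- as.character(months_needed)

  auc_rows <- vector("list", length(years))
  for (i in seq_along(years)) {
    yr <- years[i]
    res <- year_auc(S[, as.character(12 * yr)], df$follow_up_months,
                    df$graft_loss, yr, n_boot = n_boot,
                    seed = if (is.null(seed)) NULL else derive_seed(seed, yr))
    auc_rows[[i]] <- as.data.frame(res)
  }
  auc_by_year <- do.call(rbind, auc_rows)

  s_h <- S[, as.character(horizon)]
  calib <- calibration_table(s_h, df$follow_up_months, df$graft_loss,
                             groups = min(groups, nrow(df)),
                             horizon = horizon)
  # HL at subject level: event by `horizon` vs predicted event probability;
  # subjects censored before the horizon without an event are not classifiable
  hl_eligible <- (df$graft_loss & df$follow_up_months <= horizon) |
    df$follow_up_months > horizon
  hl <- hosmer_lemeshow(1 - s_h[hl_eligible],
                        as.numeric(df$graft_loss[hl_eligible] &
                                     df$follow_up_months[hl_eligible] <= horizon),
                        groups = min(groups, sum(hl_eligible)))
  structure(list(label = label, horizon = horizon,
                 n_subjects = nrow(df),
                 auc_by_year = auc_by_year,
                 calibration = calib,
                 hl = hl[c("statistic", "df", "p_value", "n_merged")]),
            class = "validation_report")
}

#' Internal validation report
#'
#' Composes [year_auc()] per year, the decile [calibration_table()] and the
#' [hosmer_lemeshow()] test at the horizon into one report.  Years with no
#' eligible case or control are reported with missing AUC, never fabricated.
#' An AUC above 0.7 is conventionally annotated as good discrimination.
#'
#' @param model a converged `hazard_fit`.
#' @param cohort validation cohort.
#' @param years anniversaries to evaluate (default 1:15).
#' @param horizon calibration/HL horizon in months (default 60).
#' @param groups calibration/HL groups (default 10).
#' @param n_boot bootstrap resamples per year for AUC CIs.
#' @param seed integer seed.
#' @param label cohort label carried into the report.
#' @return a `validation_report`.
#' @export
internal_validate <- function(model, cohort, years = 1:15, horizon = 60L,
                              groups = 10L, n_boot = 2000L, seed = NULL,
                              label = "internal") {
  validate_cohort(model, cohort, years, horizon, groups, n_boot, seed, label)
}

#' External validation report
#'
#' Applies a fitted model *unchanged* (no refit) to a full external cohort
#' and produces the same report structure as [internal_validate()].
#' Category levels that the model cannot encode raise a validation error
#' listing the offending levels.
#'
#' @inheritParams internal_validate
#' @export
external_validate <- function(model, cohort, years = 1:15, horizon = 60L,
                              groups = 10L, n_boot = 2000L, seed = NULL,
                              label = "external") {
  df <- as.data.frame(cohort)
  bad_dis <- setdiff(unique(df$primary_disease),
                     model$encoding$disease_levels)
  if (length(bad_dis)) {
    stop("unmappable primary_disease level(s): ",
         paste(bad_dis, collapse = ", "))
  }
  if (!is.null(model$encoding$country_levels)) {
    bad_c <- setdiff(unique(df$country), model$encoding$country_levels)
    if (length(bad_c)) {
      stop("unmappable country level(s): ", paste(bad_c, collapse = ", "))
    }
  }
  validate_cohort(model, cohort, years, horizon, groups, n_boot, seed, label)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation report [%s]: %d subjects, horizon %d months\n",
              x$label, x$n_subjects, x$horizon))
  aucs <- x$auc_by_year
  shown <- aucs[aucs$year %in% c(1, 5, 10, 15) & !is.na(aucs$auc), ]
  if (nrow(shown)) {
    for (i in seq_len(nrow(shown))) {
      cat(sprintf("  year %2d AUC %.2f (95%% CI %.2f-%.2f)%s\n",
                  shown$year[i], shown$auc[i], shown$ci_lower[i],
                  shown$ci_upper[i],
                  if (!is.na(shown$auc[i]) && shown$auc[i] > 0.7) "  [good]" else ""))
    }
  }
  cat(sprintf("  Hosmer-Lemeshow: %.3f on %d df (P = %.2f)\n",
              x$hl$statistic, x$hl$df, x$hl$p_value))
  invisible(x)
}

#' Serialise a validation report to JSON
#'
#' @param report a `validation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  obj <- unclass(report)
  obj$type <- "pktsurv_validation_report"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' Read a validation report serialised by [write_validation_report()]
#'
#' @param path JSON path.
#' @return a `validation_report`.
#' @export
read_validation_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "pktsurv_validation_report")) {
    stop(path, " is not a serialised validation report")
  }
  obj$type <- NULL
  obj$auc_by_year <- as.data.frame(obj$auc_by_year)
  obj$calibration <- as.data.frame(obj$calibration)
  structure(obj, class = "validation_report")
}
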