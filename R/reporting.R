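# Registry-style cohort description, Kaplan-Meier estimation and log-rank
# comparison.

fmt_pct_n <- function(count, total) {
  sprintf("%d (%d)", round_half_up(100 * count / total), count)
}

fmt_median_iqr <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
  sprintf("%d [%d–%d]", round_half_up(q[2L]), round_half_up(q[1L]),
          round_half_up(q[3L]))
}

#' Cohort characteristics table
#'
#' One row per variable, one summary column per cohort: continuous variables
#' as `median [Q1-Q3]` with a Kruskal-Wallis test across cohorts (with tie
#' correction); binary/categorical variables as `pct (n)` (percentages
#' rounded half-up to integers) with a chi-squared test of homogeneity
#' (without continuity correction).  Each disease category is tested as its
#' own presence/absence row, as registry tables usually print it.  With a
#' single cohort the tests are omitted.
#'
#' @param cohorts named list of `transplant_cohort`s.
#' @return data.frame: `variable`, one column per cohort label, `test`,
#'   `statistic`, `p_value`.
#' @export
summarize_cohorts <- function(cohorts) {
  if (!length(cohorts)) stop("need at least one cohort")
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts)))) {
    stop("cohorts must be a named list")
  }
  labels <- names(cohorts)
  dfs <- lapply(cohorts, as.data.frame)
  multi <- length(dfs) > 1L

  continuous <- c(follow_up_months = "Follow-up (m)",
                  recipient_age = "Recipient age",
                  donor_age = "Donor age",
                  hla_mm = "HLA MM")
  binary <- c(graft_loss = "Graft loss",
              living_donor = "LD",
              preemptive = "Pre-emptive PKT",
              retransplant = "Re-transplant")

  for (v in c(names(continuous), names(binary), "primary_disease")) {
    missing_from <- labels[!vapply(dfs, function(d) v %in% names(d), TRUE)]
    if (length(missing_from)) {
      stop("variable '", v, "' absent from cohort(s): ",
           paste(missing_from, collapse = ", "))
    }
  }

  rows <- list()
  add_row <- function(variable, summaries, test, statistic, p_value) {
    r <- c(list(variable = variable), as.list(summaries),
           list(test = test, statistic = statistic, p_value = p_value))
    rows[[length(rows) + 1L]] <<- as.data.frame(r, check.names = FALSE)
  }

  for (v in names(continuous)) {
    summaries <- setNames(vapply(dfs, function(d) fmt_median_iqr(d[[v]]),
                                 ""), labels)
    if (multi) {
      x <- unlist(lapply(dfs, function(d) d[[v]]))
      g <- factor(rep(labels, vapply(dfs, nrow, 0L)))
      kw <- kruskal.test(x, g)
      add_row(continuous[[v]], summaries, "Kruskal-Wallis",
              unname(kw$statistic), kw$p.value)
    } else {
      add_row(continuous[[v]], summaries, NA_character_, NA_real_, NA_real_)
    }
  }
  for (v in names(binary)) {
    counts <- vapply(dfs, function(d) sum(d[[v]], na.rm = TRUE), 0L)
    totals <- vapply(dfs, nrow, 0L)
    summaries <- setNames(mapply(fmt_pct_n, counts, totals), labels)
    if (multi) {
      tab <- rbind(counts, totals - counts)
      ch <- suppressWarnings(chisq.test(tab, correct = FALSE))
      add_row(binary[[v]], summaries, "Chi-squared",
              unname(ch$statistic), ch$p.value)
    } else {
      add_row(binary[[v]], summaries, NA_character_, NA_real_, NA_real_)
    }
  }
  for (lv in disease_levels()) {
    counts <- vapply(dfs, function(d)
      sum(d$primary_disease == lv, na.rm = TRUE), 0L)
    totals <- vapply(dfs, nrow, 0L)
    summaries <- setNames(mapply(fmt_pct_n, counts, totals), labels)
    if (multi) {
      tab <- rbind(counts, totals - counts)
      ch <- suppressWarnings(chisq.test(tab, correct = FALSE))
      add_row(lv, summaries, "Chi-squared", unname(ch$statistic), ch$p.value)
    } else {
      add_row(lv, summaries, NA_character_, NA_real_, NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of graft survival; death with a functioning graft
#' or end of follow-up is censoring.
#'
#' @param follow_up months of follow-up (>= 1).
#' @param event graft-loss indicator.
#' @param group optional group labels (one estimate per group).
#' @return data.frame `(group, time, n_risk, n_event, survival)`.
#' @export
km_estimate <- function(follow_up, event, group = NULL) {
  if (any(follow_up < 1)) stop("follow_up must be >= 1")
  group <- group %||% rep("all", length(follow_up))
  out <- lapply(unique(group), function(g) {
    in_g <- group == g
    fit <- survival::survfit(
      survival::Surv(follow_up[in_g], as.integer(event[in_g])) ~ 1)
    data.frame(group = g, time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, survival = fit$surv)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("km_estimate", "data.frame")
  res
}

#' Log-rank test
#'
#' Standard log-rank chi-square comparing two or more groups, df = groups - 1.
#'
#' @param follow_up months of follow-up.
#' @param event graft-loss indicator.
#' @param group group labels (at least two groups, at least one event).
#' @return list `(statistic, df, p_value)`.
#' @export
log_rank <- function(follow_up, event, group) {
  g <- factor(group)
  if (nlevels(g) < 2L) stop("log-rank test needs at least 2 groups")
  if (sum(event) < 1L) stop("log-rank test needs at least 1 event")
  sd <- survival::survdiff(survival::Surv(follow_up, as.integer(event)) ~ g)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = pchisq(sd$chisq, df, lower.tail = FALSE))
}
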