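test_that("derivation/validation split is sized, disjoint and seeded", {
  reg <- generate_registry(default_profiles(), seed = 30)
  halves <- split_cohort(reg, 0.8, seed = 1)
  expect_equal(nrow(halves$derivation), 1980L)
  expect_equal(nrow(halves$validation), 495L)
  expect_length(intersect(halves$derivation$subject_id,
                          halves$validation$subject_id), 0L)
  expect_setequal(c(halves$derivation$subject_id,
                    halves$validation$subject_id), reg$subject_id)

  again <- split_cohort(reg, 0.8, seed = 1)
  expect_identical(as.data.frame(again$derivation),
                   as.data.frame(halves$derivation))

  expect_error(split_cohort(reg, 1.0), "between 0 and 1")
  expect_error(split_cohort(reg, 0), "between 0 and 1")
  expect_error(split_cohort(toy_cohort(5), 0.8), "at least 10")
})

test_that("time-dependent AUC handles perfect, null and censored cases", {
  # perfectly separating scores
  fu <- c(rep(6L, 10), rep(40L, 10))
  ev <- rep(c(TRUE, FALSE), each = 10)
  surv <- c(rep(0.2, 10), rep(0.9, 10))
  res <- year_auc(surv, fu, ev, year = 1, n_boot = 50, seed = 1)
  expect_equal(res$auc, 1.0)
  expect_equal(res$n_cases, 10L)
  expect_equal(res$n_controls, 10L)
  expect_true(res$ci_lower <= res$auc && res$auc <= res$ci_upper)

  # scores independent of outcome stay near 1/2
  set.seed(2)
  n <- 2000
  fu2 <- sample(c(5L, 30L), n, replace = TRUE)
  ev2 <- fu2 == 5L
  surv2 <- runif(n)
  res2 <- year_auc(surv2, fu2, ev2, year = 1, n_boot = 0)
  null_se <- sqrt((res2$n_cases + res2$n_controls + 1) /
                    (12 * res2$n_cases * res2$n_controls))
  expect_lt(abs(res2$auc - 0.5), 3 * null_se)

  # early-censored subjects are excluded; death with function past t is a
  # control
  fu3 <- c(3L, 13L, 6L, 20L)
  ev3 <- c(FALSE, FALSE, TRUE, FALSE)
  surv3 <- c(0.1, 0.8, 0.2, 0.9)
  res3 <- year_auc(surv3, fu3, ev3, year = 1, n_boot = 0)
  expect_equal(res3$n_cases, 1L)
  expect_equal(res3$n_controls, 2L)

  # no cases -> missing, not fabricated
  res4 <- year_auc(c(0.5, 0.6), c(20L, 30L), c(FALSE, FALSE), 1, n_boot = 0)
  expect_true(is.na(res4$auc))
})

test_that("AUC equals brute-force pairwise concordance on small instances", {
  for (s in 1:20) {
    set.seed(400 + s)
    n <- sample(10:50, 1)
    fu <- sample(1:30, n, replace = TRUE)
    ev <- runif(n) < 0.5
    surv <- round(runif(n), 2)  # many ties
    res <- year_auc(surv, fu, ev, year = 1, n_boot = 0)
    is_case <- ev & fu <= 12
    is_ctrl <- fu > 12
    if (sum(is_case) == 0 || sum(is_ctrl) == 0) {
      expect_true(is.na(res$auc))
    } else {
      keep <- is_case | is_ctrl
      expect_equal(res$auc,
                   brute_force_auc((1 - surv)[keep], is_case[keep]),
                   tolerance = 1e-12)
    }
  }
})

test_that("calibration bins are balanced and reduce to empirical fractions", {
  # identical predictions: stable tie-break still yields equal bins
  n <- 100
  tab <- calibration_table(rep(0.8, n), rep(30L, n),
                           rep(c(TRUE, FALSE), 50), groups = 10,
                           horizon = 24)
  expect_equal(tab$n, rep(10L, 10))
  expect_equal(sum(tab$n), n)

  # without censoring the KM observed equals the empirical fraction
  set.seed(5)
  surv <- runif(200)
  ev <- runif(200) < 0.3
  fu <- ifelse(ev, sample(1:24, 200, TRUE), 36L)
  tab2 <- calibration_table(surv, fu, ev, groups = 5, horizon = 24)
  ord <- order(surv, seq_along(surv))
  bins <- integer(200)
  bins[ord] <- rep(1:5, each = 40)
  for (g in 1:5) {
    expect_equal(tab2$observed[g], 1 - mean(ev[bins == g]),
                 tolerance = 1e-12)
  }
  expect_error(calibration_table(runif(5), rep(10L, 5), rep(FALSE, 5),
                                 groups = 10, horizon = 6), "exceed")
})

test_that("Hosmer-Lemeshow is exact on perfect fits and merges empty cells", {
  # observed = expected exactly in every group
  p <- rep(c(0.2, 0.4, 0.5, 0.8), each = 10)
  y <- c(rep(c(1, 0, 0, 0, 0), 2),        # 2 events where p = 0.2
         rep(c(1, 1, 0, 0, 0), 2),        # 4 events where p = 0.4
         rep(c(1, 0), 5),                 # 5 events where p = 0.5
         rep(c(1, 1, 1, 1, 0), 2))        # 8 events where p = 0.8
  hl <- hosmer_lemeshow(p, y, groups = 4)
  expect_equal(hl$statistic, 0)
  expect_equal(hl$p_value, 1)
  expect_equal(hl$df, 2L)

  # a zero expected cell is merged and df reduced
  p2 <- c(rep(0, 10), runif(90, 0.2, 0.8))
  y2 <- c(rep(0, 10), rbinom(90, 1, 0.5))
  hl2 <- hosmer_lemeshow(p2, y2, groups = 10)
  expect_gt(hl2$n_merged, 0L)
  expect_equal(hl2$df, nrow(hl2$table) - 2L)
  expect_gte(hl2$statistic, 0)

  expect_error(hosmer_lemeshow(runif(5), rbinom(5, 1, 0.5), groups = 10),
               "at least")
})

test_that("validation reports compose, serialise and round-trip", {
  reg <- generate_registry(default_profiles(), seed = 33,
                           sizes = c(60, 200, 60, 50))
  dev <- reestimate(reg, seed = 34, years = c(1, 3, 5), n_boot = 25)
  rep1 <- dev$report
  expect_s3_class(rep1, "validation_report")
  expect_true(all(rep1$auc_by_year$year == c(1, 3, 5)))
  ok <- !is.na(rep1$auc_by_year$auc)
  expect_true(all(rep1$auc_by_year$auc[ok] >= 0 &
                    rep1$auc_by_year$auc[ok] <= 1))
  expect_true(all(rep1$auc_by_year$ci_lower[ok] <= rep1$auc_by_year$auc[ok]))
  expect_equal(sum(rep1$calibration$n), rep1$n_subjects)

  path <- withr::local_tempfile(fileext = ".json")
  write_validation_report(rep1, path)
  back <- read_validation_report(path)
  expect_equal(back$auc_by_year$auc, rep1$auc_by_year$auc, tolerance = 1e-12)
  expect_equal(back$hl$statistic, rep1$hl$statistic, tolerance = 1e-12)
  expect_equal(back$calibration$observed, rep1$calibration$observed,
               tolerance = 1e-12)

  # years beyond the data are flagged missing, never fabricated
  far <- internal_validate(dev$model, reg, years = c(1, 30), horizon = 24,
                           n_boot = 0)
  expect_true(is.na(far$auc_by_year$auc[far$auc_by_year$year == 30]))
})

test_that("external validation equals internal on the same cohort", {
  reg <- generate_registry(default_profiles(), seed = 35,
                           sizes = c(60, 200, 60, 50))
  dev <- reestimate(reg, seed = 36, years = 1:3, n_boot = 10)
  int <- internal_validate(dev$model, dev$validation, years = 1:3,
                           n_boot = 10, seed = 9)
  ext <- external_validate(dev$model, dev$validation, years = 1:3,
                           n_boot = 10, seed = 9)
  expect_equal(ext$auc_by_year, int$auc_by_year, tolerance = 1e-12)
  expect_equal(ext$hl$statistic, int$hl$statistic, tolerance = 1e-12)

  # unmappable categories are reported by name
  other <- as.data.frame(dev$validation)
  other$primary_disease[1] <- "glomerulopathy"
  other_cohort <- new_cohort(other)
  expect_silent({r <- external_validate(dev$model, other_cohort,
                                        years = 2, n_boot = 0)})
  dev2 <- reestimate(reg, spec = hazard_spec(country_dummies = TRUE),
                     seed = 37, years = 2, n_boot = 0)
  bad <- as.data.frame(dev2$validation)
  bad$country <- "XX"
  expect_error(external_validate(dev2$model, new_cohort(bad), years = 2,
                                 n_boot = 0),
               "unmappable country")
})

test_that("a shifted truth intercept is caught by the Hosmer-Lemeshow test", {
  tr <- default_truth_model(study_end_year = NULL)
  tr$dropout_rate <- 0
  tr$death_rate <- 0
  shifted <- tr
  shifted$intercept <- tr$intercept + 0.5
  prof <- default_profiles()$FR
  rejections <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    cov <- sample_covariates(prof, 400, seed = 700 + r)
    sim <- simulate_outcomes(cov, shifted, seed = 800 + r)
    # predictions from the unshifted model are miscalibrated
    s60 <- truth_survival(tr, sim, months = 60)[, 1]
    y <- as.numeric(sim$graft_loss & sim$follow_up_months <= 60)
    hl <- hosmer_lemeshow(1 - s60, y)
    if (!is.na(hl$p_value) && hl$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / n_rep, 0.5)
})
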