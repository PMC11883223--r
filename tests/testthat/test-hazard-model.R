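test_that("person-period expansion conserves rows and places events last", {
  co <- toy_cohort(3, follow_up = c(3L, 5L, 12L),
                   graft_loss = c(TRUE, FALSE, TRUE))
  pp <- expand_person_period(co)
  expect_equal(nrow(pp), 20L)
  expect_equal(sum(pp$event), 2L)

  one <- pp[pp$subject_id == "S001", ]
  expect_equal(one$month, 1:3)
  expect_equal(one$event, c(0L, 0L, 1L))

  censored <- pp[pp$subject_id == "S002", ]
  expect_equal(censored$event, rep(0L, 5))

  # death with functioning graft is censoring, not an event
  co2 <- toy_cohort(1, follow_up = 4L, death_with_function = TRUE)
  pp2 <- expand_person_period(co2)
  expect_equal(sum(pp2$event), 0L)

  co3 <- toy_cohort(1)
  co3$follow_up_months <- NA_integer_
  expect_error(expand_person_period(co3), "follow_up_months")
})

test_that("intercept-only fit equals the closed-form event-rate MLE", {
  pp <- data.frame(subject_id = as.character(1:60), month = 1,
                   event = rep(c(1L, 0L), c(9, 51)), weight = 1)
  fit <- fit_hazard(pp, hazard_spec(covariates = character(0)))
  expect_true(fit$converged)
  expect_equal(fit$intercept, qlogis(9 / 60), tolerance = 1e-6)
  expect_length(fit$beta, 0L)
})

test_that("fitted coefficients match an exhaustive likelihood grid search", {
  # 40-row toy: binary covariate, event counts chosen off any closed pattern
  x <- rep(c(1, 0), c(18, 22))
  y <- c(rep(1L, 7), rep(0L, 11), rep(1L, 3), rep(0L, 19))
  pp <- data.frame(subject_id = as.character(1:40), month = 1,
                   event = y, x = x, weight = 1)
  fit <- fit_hazard(pp, hazard_spec(covariates = "x"))
  grid <- grid_mle_1cov(n11 = 7, n10 = 11, n01 = 3, n00 = 19)
  expect_equal(unname(fit$intercept), grid[1], tolerance = 1e-3)
  expect_equal(unname(fit$beta[["x"]]), grid[2], tolerance = 1e-3)
  # the binary single-covariate MLE also has a closed form
  expect_equal(unname(fit$intercept), qlogis(3 / 22), tolerance = 1e-6)
  expect_equal(unname(fit$beta[["x"]]), qlogis(7 / 18) - qlogis(3 / 22),
               tolerance = 1e-6)
})

test_that("fit agrees with an independent IRLS implementation (glm)", {
  reg <- generate_registry(default_profiles(), seed = 21, sizes = c(60, 150, 60, 40))
  pp <- expand_person_period(reg)
  spec <- place_knots(pp$month)
  pp <- add_spline_basis(pp, spec)
  fit <- fit_hazard(pp)
  g <- stats::glm(
    event ~ recipient_age + donor_age + living_donor + preemptive +
      retransplant + hla_mm + hla_dr_mm +
      factor(primary_disease, levels = disease_levels()) +
      time_ns1 + time_ns2 + time_ns3 + time_ns4 + time_ns5,
    family = stats::binomial(), data = pp,
    control = stats::glm.control(epsilon = 1e-12))
  expect_equal(unname(coef(fit)), unname(coef(g)), tolerance = 1e-6)
  expect_equal(fit$log_likelihood, as.numeric(stats::logLik(g)),
               tolerance = 1e-8)

  # unit weights equal the unweighted fit exactly
  fit_w <- fit_hazard(pp, weights = rep(1, nrow(pp)))
  expect_equal(coef(fit_w), coef(fit), tolerance = 1e-10)

  # non-trivial weights agree with weighted glm
  w <- rep(c(1, 2.5), length.out = nrow(pp))
  fit_w2 <- fit_hazard(pp, weights = w)
  g2 <- suppressWarnings(stats::glm(
    event ~ recipient_age + donor_age + living_donor + preemptive +
      retransplant + hla_mm + hla_dr_mm +
      factor(primary_disease, levels = disease_levels()) +
      time_ns1 + time_ns2 + time_ns3 + time_ns4 + time_ns5,
    family = stats::binomial(), data = pp, weights = w,
    control = stats::glm.control(epsilon = 1e-12)))
  expect_equal(unname(coef(fit_w2)), unname(coef(g2)), tolerance = 1e-5)
})

test_that("separation is detected and a ridge penalty rescues it", {
  pp <- data.frame(subject_id = as.character(1:20), month = 1,
                   event = rep(c(1L, 0L), each = 10),
                   x = rep(c(1, 0), each = 10), weight = 1)
  expect_error(fit_hazard(pp, hazard_spec(covariates = "x")), "separation")
  fit <- fit_hazard(pp, hazard_spec(covariates = "x", penalty = 1e-6))
  expect_true(fit$converged)
  expect_true(is.finite(fit$beta[["x"]]))

  expect_error(fit_hazard(pp[pp$event == 0, ],
                          hazard_spec(covariates = "x")), "no events")
})

test_that("predicted hazards follow the logistic form and monotonicity", {
  m0 <- make_model(0)
  expect_equal(predict_hazard(m0, toy_cohort(1), 1:24), rep(0.5, 24))

  m <- make_model(-2, beta = c(donor_age = 0.05))
  rec <- toy_cohort(1)
  expect_equal(predict_hazard(m, rec, 1),
               plogis(-2 + 0.05 * 35), tolerance = 1e-12)
  h <- vapply(c(10, 20, 40, 60), function(a) {
    r <- rec; r$donor_age <- a
    predict_hazard(m, r, 1)
  }, 0)
  expect_true(all(diff(h) > 0))

  expect_error(predict_hazard(m, rec, 0), "month")
})

test_that("survival curves multiply hazards and respect the identity", {
  m <- make_model(0)  # constant hazard 1/2
  sc <- predict_survival(m, toy_cohort(1), 12)
  expect_equal(sc$survival[12], 0.5^12, tolerance = 1e-12)

  m2 <- make_model(-30)
  sc2 <- predict_survival(m2, toy_cohort(1), 24)
  expect_true(all(sc2$survival > 1 - 1e-6))

  m3 <- make_model(-3, beta = c(hla_mm = 0.2),
                   gamma = c(-0.2, -0.4, -0.5, -0.6, -0.7),
                   spline = spline_spec(c(5, 20, 40, 55), c(1, 60)))
  sc3 <- predict_survival(m3, toy_cohort(1), 60)
  expect_true(all(diff(sc3$survival) < 0))
  expect_equal(sc3$survival[-60] * (1 - sc3$hazard[-1]), sc3$survival[-1],
               tolerance = 1e-12)
})

test_that("donor scenario comparison composes single predictions", {
  reg <- generate_registry(default_profiles(), seed = 22,
                           sizes = c(40, 120, 40, 30))
  dev <- reestimate(reg, seed = 23, years = 1:3, n_boot = 0)
  rec <- as.data.frame(reg)[5, ]

  same <- compare_scenarios(dev$model, rec,
                            list(a = list(hla_mm = 2), b = list(hla_mm = 2)),
                            horizon = 36)
  expect_equal(same$a$survival, same$b$survival)

  rec2 <- rec
  rec2$hla_mm <- 2
  direct <- predict_survival(dev$model, rec2, 36)
  expect_equal(same$a$survival, direct$survival)

  expect_error(compare_scenarios(dev$model, rec,
                                 list(x = list(recipient_age = 2)), 36),
               "donor-side")
})

test_that("coefficient bias shrinks as the cohort grows", {
  tr <- default_truth_model(study_end_year = NULL)
  tr$admin_horizon <- 120L
  profs <- default_profiles()
  bin <- c("living_donor", "preemptive", "retransplant")
  bias_at <- function(n, seeds) {
    errs <- sapply(seeds, function(s) {
      cov <- generate_registry(profs, truth = tr, seed = s,
                               sizes = round(n * c(0.11, 0.65, 0.15, 0.09)))
      pp <- expand_person_period(cov)
      pp <- add_spline_basis(pp, place_knots(pp$month))
      fit <- fit_hazard(pp)
      abs(fit$beta[bin] - unlist(tr$beta[bin]))
    })
    mean(errs)
  }
  mae_small <- bias_at(500, 31:33)
  mae_large <- bias_at(3000, 31:33)
  expect_lt(mae_large, mae_small)
  expect_lt(mae_large, 0.15)
})

test_that("models serialise to JSON and back without loss", {
  reg <- generate_registry(default_profiles(), seed = 24,
                           sizes = c(40, 120, 40, 30))
  dev <- reestimate(reg, seed = 25, years = 1:2, n_boot = 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_hazard_model(dev$model, path)
  back <- read_hazard_model(path)
  expect_equal(coef(back), coef(dev$model), tolerance = 1e-12)
  expect_equal(back$spline_spec$interior_knots,
               dev$model$spline_spec$interior_knots)
  sc1 <- predict_survival(dev$model, as.data.frame(reg)[1, ], 60)
  sc2 <- predict_survival(back, as.data.frame(reg)[1, ], 60)
  expect_equal(sc1$survival, sc2$survival, tolerance = 1e-12)
})
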