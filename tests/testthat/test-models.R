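# Model sequence, likelihood-ratio tests, EMM profiles, diagnostics, and
# the boosted-tree attribution model.

test_that("the model sequence adds 5, 10 and 23 fixed parameters", {
  qc <- quick_cohort(n = 50, seed = 2)
  ms <- suppressWarnings(fit_model_sequence(qc$rows, objectives = "ML"))
  p <- vapply(c("m1", "m2", "m3", "m4"),
              function(m) ms$summaries[[paste0(m, "_ML")]]$n_fixed_params,
              integer(1))
  expect_equal(unname(p), c(1L, 6L, 16L, 39L))
  expect_equal(lrt(ms$fits$ML$m1, ms$fits$ML$m2)$df, 5L)
  expect_equal(lrt(ms$fits$ML$m2, ms$fits$ML$m3)$df, 10L)
  expect_equal(lrt(ms$fits$ML$m3, ms$fits$ML$m4)$df, 23L)
})

test_that("model preconditions: two patients minimum, complete covariates", {
  qc <- quick_cohort(n = 20, seed = 6)
  one <- qc$rows[qc$rows$patient_id == qc$rows$patient_id[1], ]
  expect_error(fit_model_sequence(one), class = "glucirc_domain_error")
  broken <- qc$rows
  broken$diabetes[3] <- NA
  expect_error(prepare_model_data(broken), class = "glucirc_domain_error")
})

test_that("likelihood-ratio test handles identity, nesting and objective checks", {
  qc <- quick_cohort(n = 30, seed = 9)
  ms <- suppressWarnings(fit_model_sequence(qc$rows, models = c("m2", "m3")))
  # identical models: chi-square 0, p 1
  same <- lrt(ms$fits$ML$m2, ms$fits$ML$m2)
  expect_equal(same$chi_square, 0)
  expect_equal(same$df, 0L)
  expect_equal(same$p_value, 1)
  # swapped nesting is an error
  expect_error(lrt(ms$fits$ML$m3, ms$fits$ML$m2),
               class = "glucirc_domain_error")
  # REML fits are refused
  expect_error(lrt(ms$fits$REML$m2, ms$fits$REML$m3),
               class = "glucirc_domain_error")
  # statistic arithmetic
  l <- lrt(ms$fits$ML$m2, ms$fits$ML$m3)
  expect_equal(l$chi_square,
               2 * (as.numeric(logLik(ms$fits$ML$m3)) -
                    as.numeric(logLik(ms$fits$ML$m2))))
  expect_equal(l$p_value, pchisq(l$chi_square, 10, lower.tail = FALSE))
})

test_that("EMM equals the closed-form average of fixed effects", {
  qc <- quick_cohort(n = 60, seed = 15)
  ms <- suppressWarnings(fit_model_sequence(qc$rows, models = "m4",
                                            objectives = "ML"))
  fit <- ms$fits$ML$m4
  prof <- emm_profile(fit)
  beta <- lme4::fixef(fit)
  # manual formula: intercept + hour effect + mean over each covariate's
  # level effects (reference level contributes 0)
  cov_means <-
    mean(c(0, beta[c("age_cat55-65", "age_cat66-75", "age_cat>75")])) +
    mean(c(0, beta["sexmale"])) +
    mean(c(0, beta["diabetesyes"])) +
    mean(c(0, beta[c("carb_cat4.5<x<=6.5", "carb_cat6.5<x<=8.5", "carb_cat>8.5")])) +
    mean(c(0, beta[c("insulin_cat0<x<=1.5", "insulin_cat1.5<x<=3", "insulin_cat>3")])) +
    mean(c(0, beta[c("dextrose_cat0<x<=0.5", "dextrose_cat0.5<x<=2", "dextrose_cat>2")])) +
    mean(c(0, beta["glucocorticoidyes"]))
  hour_eff <- c(0, beta[grep("^hour_factor", names(beta))])
  manual <- unname(beta["(Intercept)"] + cov_means + hour_eff)
  expect_equal(prof$emm, manual, tolerance = 1e-10)
  # peak/trough bookkeeping is consistent with the profile
  s <- emm_summary(prof)
  expect_equal(prof$emm[prof$hour == s$peak_hour], max(prof$emm))
  expect_equal(prof$emm[prof$hour == s$trough_hour], min(prof$emm))
  expect_equal(s$amplitude, max(prof$emm) - min(prof$emm))
})

test_that("EMM point estimates and standard errors match the emmeans oracle", {
  qc <- quick_cohort(n = 60, seed = 15)
  ms <- suppressWarnings(fit_model_sequence(qc$rows, models = "m4",
                                            objectives = "ML"))
  emmeans::emm_options(rg.limit = 60000)
  em <- as.data.frame(
    emmeans::emmeans(ms$fits$ML$m4, ~hour_factor, lmer.df = "asymptotic")
  )
  prof <- emm_profile(ms$fits$ML$m4)
  expect_equal(prof$emm, em$emmean, tolerance = 1e-8)
  expect_equal(prof$se, em$SE, tolerance = 1e-8)
})

test_that("frequency weighting reproduces the observed-margin average", {
  qc <- quick_cohort(n = 50, seed = 23)
  ms <- suppressWarnings(fit_model_sequence(qc$rows, models = "m4",
                                            objectives = "ML"))
  fit <- ms$fits$ML$m4
  prof_eq <- emm_profile(fit)
  prof_fr <- emm_profile(fit, weighting = "frequency")
  expect_false(isTRUE(all.equal(prof_eq$emm, prof_fr$emm)))
  # cross-check against emmeans with proportional weights
  emmeans::emm_options(rg.limit = 60000)
  em <- as.data.frame(
    emmeans::emmeans(fit, ~hour_factor, weights = "proportional",
                     lmer.df = "asymptotic")
  )
  expect_equal(prof_fr$emm, em$emmean, tolerance = 1e-8)
})

test_that("hour-only model EMMs equal the raw hourly mixed-model means", {
  qc <- quick_cohort(n = 40, seed = 27)
  d <- prepare_model_data(qc$rows)
  fit <- lme4::lmer(glucose_mmol_l ~ hour_factor + (1 | patient_id),
                    data = d, REML = FALSE)
  prof <- emm_profile(fit)
  beta <- lme4::fixef(fit)
  expect_equal(prof$emm,
               unname(beta[1] + c(0, beta[grep("hour_factor", names(beta))])),
               tolerance = 1e-10)
})

test_that("flat truth yields a flat profile at the intercept", {
  zero <- list(age = c("55-65" = 0, "66-75" = 0, ">75" = 0), sex_male = 0,
               diabetes = 0, carb = c("4.5<x<=6.5" = 0, "6.5<x<=8.5" = 0, ">8.5" = 0),
               insulin = c("0<x<=1.5" = 0, "1.5<x<=3" = 0, ">3" = 0),
               dextrose = c("0<x<=0.5" = 0, "0.5<x<=2" = 0, ">2" = 0),
               glucocorticoid = 0)
  g <- generate_cohort(synth_config(
    n_patients = 30, seed = 41, true_time_effect = rep(0, 24),
    true_coefficients = zero, residual_sd = 0.01,
    random_intercept_sd = 0.01, fraction_invalid = 0
  ))
  rows <- suppressWarnings(build_analysis_table(g$tables))$rows
  ms <- suppressWarnings(fit_model_sequence(rows, models = "m4",
                                            objectives = "ML"))
  prof <- emm_profile(ms$fits$ML$m4)
  # values are stored rounded to 0.1 mmol/L, so the profile is flat to
  # within the rounding grain
  expect_lt(attr(prof, "amplitude"), 0.1)
  expect_equal(prof$emm, rep(6.6, 24), tolerance = 0.06)
})

test_that("coefficient recovery: diabetes CI covers the true 2.2 across seeds", {
  st <- recovery_study(n_seeds = 5, n_patients = 150, base_seed = 7)
  diab <- st$coverage[st$coverage$term == "diabetesyes", ]
  expect_gte(sum(diab$covered), 4)
  expect_equal(mean(diab$estimate), 2.2, tolerance = 0.25)
  # pooled CI coverage across all terms behaves like a 95% interval
  expect_gte(st$pooled_coverage, 0.85)
})

test_that("null truth recovers near-zero coefficients", {
  zero <- list(age = c("55-65" = 0, "66-75" = 0, ">75" = 0), sex_male = 0,
               diabetes = 0, carb = c("4.5<x<=6.5" = 0, "6.5<x<=8.5" = 0, ">8.5" = 0),
               insulin = c("0<x<=1.5" = 0, "1.5<x<=3" = 0, ">3" = 0),
               dextrose = c("0<x<=0.5" = 0, "0.5<x<=2" = 0, ">2" = 0),
               glucocorticoid = 0)
  st <- recovery_study(
    n_seeds = 5, n_patients = 150, base_seed = 5,
    config_fn = function(n, seed) {
      synth_config(n_patients = n, seed = seed,
                   true_time_effect = rep(0, 24), true_coefficients = zero)
    }
  )
  non_int <- st$coverage[st$coverage$term != "(Intercept)", ]
  expect_gte(mean(non_int$covered), 0.9)
  expect_lt(abs(mean(non_int$estimate)), 0.1) # no systematic bias
})

test_that("residual diagnostics are centred, deterministic and near-Gaussian", {
  qc <- quick_cohort(n = 350, seed = 3)
  expect_gt(nrow(qc$rows), 9000)
  ms <- suppressWarnings(fit_model_sequence(qc$rows, models = "m4",
                                            objectives = "REML"))
  d1 <- model_diagnostics(ms$fits$REML$m4)
  d2 <- model_diagnostics(ms$fits$REML$m4)
  expect_identical(d1$resid_fitted, d2$resid_fitted)
  expect_lt(abs(d1$mean), 1e-6)
  expect_lt(abs(d1$skewness), 0.2)
  expect_equal(sum(d1$resid_fitted$n), nrow(qc$rows))
})

test_that("attribution values are additive and small cohorts use all rows", {
  qc <- quick_cohort(n = 60, seed = 10)
  expect_message(sp <- fit_gbm_shap(qc$rows, seed = 2), "all of them")
  shap_cols <- paste0("shap_", c("hour_bin", "age_years", "sex_male",
                                 "diabetes_yes", "carb_rate_g_h",
                                 "insulin_rate_u_h", "dextrose_rate_g_h",
                                 "glucocorticoid_yes"))
  recon <- rowSums(as.matrix(sp$shap[, shap_cols])) + sp$base_value
  expect_equal(recon, sp$shap$prediction, tolerance = 1e-3)
  expect_equal(nrow(sp$shap), nrow(qc$rows))
})

test_that("hour-of-day attribution ranks below diabetes when time truly has no effect", {
  null_cfg <- synth_config(n_patients = 120, seed = 61,
                           true_time_effect = rep(0, 24))
  g0 <- generate_cohort(null_cfg)
  rows0 <- suppressWarnings(build_analysis_table(g0$tables))$rows
  sp0 <- suppressMessages(fit_gbm_shap(rows0, seed = 3))
  qc <- quick_cohort(n = 120, seed = 61)
  sp1 <- suppressMessages(fit_gbm_shap(qc$rows, seed = 3))
  hour0 <- sp0$ranking$mean_abs_shap[sp0$ranking$feature == "hour_bin"]
  diab1 <- sp1$ranking$mean_abs_shap[sp1$ranking$feature == "diabetes_yes"]
  expect_lt(hour0, diab1)
})
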