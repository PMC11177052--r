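# Nested random-intercept model sequence, likelihood-ratio comparisons,
# hourly estimated-marginal-means profiles, residual diagnostics, and the
# gradient-boosted-tree cross-check.
#
# Model sequence (patient random intercept throughout):
#   m1: intercept only
#   m2: + age band, sex, diabetes                    (5 fixed params added)
#   m3: + carbohydrate, insulin, dextrose bands,
#       glucocorticoid flag                          (10 added)
#   m4: + hour of day as a 24-level factor, ref 00   (23 added)
# Variance components are reported from REML fits; likelihood-ratio tests
# and estimated marginal means use ML fits (REML log-likelihoods are not
# comparable across fixed-effect structures).

MODEL_IDS <- c("m1", "m2", "m3", "m4")

model_rhs <- function(model_id) {
  terms <- switch(model_id,
    m1 = character(0),
    m2 = c("age_cat", "sex", "diabetes"),
    m3 = c("age_cat", "sex", "diabetes", "carb_cat", "insulin_cat",
           "dextrose_cat", "glucocorticoid"),
    m4 = c("age_cat", "sex", "diabetes", "carb_cat", "insulin_cat",
           "dextrose_cat", "glucocorticoid", "hour_factor"),
    abort(paste("unknown model id:", model_id))
  )
  paste(c("1", terms, "(1 | patient_id)"), collapse = " + ")
}

#' Prepare analysis rows for model fitting
#'
#' Converts the categorical covariates to factors with fixed level order
#' (reference level first) and adds `hour_factor`, the 24-level hour-of-day
#' factor with 00:00 as reference. Aborts if any model covariate is
#' missing.
#'
#' @param rows Analysis-row tibble.
#' @return Data frame ready for [fit_model_sequence()].
#' @export
prepare_model_data <- function(rows) {
  needed <- c("glucose_mmol_l", "hour_bin", "age_cat", "sex", "diabetes",
              "carb_cat", "insulin_cat", "dextrose_cat", "glucocorticoid",
              "patient_id")
  missing_cols <- setdiff(needed, names(rows))
  if (length(missing_cols) > 0) {
    abort(paste("rows missing column(s):", paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(rows[needed])) {
    abort("model covariates must be non-missing", class = "glucirc_domain_error")
  }
  d <- as.data.frame(rows)
  d$age_cat <- factor(d$age_cat, levels = AGE_LEVELS)
  d$sex <- factor(d$sex, levels = c("female", "male"))
  d$diabetes <- factor(d$diabetes, levels = c(FALSE, TRUE), labels = c("no", "yes"))
  d$carb_cat <- factor(d$carb_cat, levels = CARB_LEVELS)
  d$insulin_cat <- factor(d$insulin_cat, levels = INSULIN_LEVELS)
  d$dextrose_cat <- factor(d$dextrose_cat, levels = DEXTROSE_LEVELS)
  d$glucocorticoid <- factor(d$glucocorticoid, levels = c(FALSE, TRUE),
                             labels = c("no", "yes"))
  d$hour_factor <- factor(sprintf("h%02d", d$hour_bin),
                          levels = sprintf("h%02d", 0:23))
  d$patient_id <- factor(d$patient_id)
  d
}

fit_one <- function(data, model_id, objective) {
  f <- as.formula(paste("glucose_mmol_l ~", model_rhs(model_id)))
  fit <- lme4::lmer(
    f, data = data, REML = identical(objective, "REML"),
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore")
  )
  if (lme4::isSingular(fit)) {
    warn(sprintf("%s (%s): singular fit (between-patient variance ~ 0)",
                 model_id, objective))
  }
  fit
}

#' Summarise one fitted mixed model
#'
#' @param fit An `lmerMod`.
#' @param model_id Model label.
#' @return List with the coefficient table (estimate, SE, Wald 95% CI,
#'   normal-approximation p), variance components, log-likelihood, fixed
#'   parameter count and fit objective.
#' @export
model_fit_summary <- function(fit, model_id = NA_character_) {
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  se <- sqrt(diag(V))
  z <- beta / se
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(
    model_id = model_id,
    coefficients = tibble(
      term = names(beta), estimate = unname(beta), std_error = unname(se),
      ci_low = unname(beta - qnorm(0.975) * se),
      ci_high = unname(beta + qnorm(0.975) * se),
      p_value = unname(2 * pnorm(-abs(z)))
    ),
    random_intercept_variance = vc$vcov[vc$grp == "patient_id"],
    residual_variance = vc$vcov[vc$grp == "Residual"],
    log_likelihood = as.numeric(logLik(fit)),
    n_fixed_params = length(beta),
    fit_objective = if (lme4::isREML(fit)) "REML" else "ML"
  )
}

#' Fit the nested random-intercept model sequence
#'
#' Fits the four-model sequence under REML (for variance components and
#' coefficient reporting) and, in parallel, under ML (for likelihood-ratio
#' tests and estimated marginal means). A singular fit (between-patient
#' variance estimated at zero) warns and is kept.
#'
#' @param rows Analysis-row tibble (or a data frame from
#'   [prepare_model_data()]).
#' @param models Subset of `c("m1","m2","m3","m4")` to fit.
#' @param objectives Subset of `c("REML", "ML")`.
#' @return A `glucirc_model_set`: nested list `fits[[objective]][[model_id]]`
#'   of `lmerMod` objects plus per-model summaries.
#' @export
fit_model_sequence <- function(rows, models = MODEL_IDS,
                               objectives = c("REML", "ML")) {
  data <- if ("hour_factor" %in% names(rows)) rows else prepare_model_data(rows)
  if (length(unique(data$patient_id)) < 2) {
    abort("at least 2 patients are required", class = "glucirc_domain_error")
  }
  models <- match.arg(models, MODEL_IDS, several.ok = TRUE)
  objectives <- match.arg(objectives, c("REML", "ML"), several.ok = TRUE)
  fits <- list()
  summaries <- list()
  for (obj in objectives) {
    fits[[obj]] <- list()
    for (mid in models) {
      fit <- fit_one(data, mid, obj)
      fits[[obj]][[mid]] <- fit
      summaries[[paste(mid, obj, sep = "_")]] <- model_fit_summary(fit, mid)
    }
  }
  structure(list(fits = fits, summaries = summaries, data = data,
                 models = models, objectives = objectives),
            class = "glucirc_model_set")
}

#' @export
print.glucirc_model_set <- function(x, ...) {
  cat("<glucirc_model_set>\n")
  for (s in x$summaries) {
    cat(sprintf("  %s (%s): %d fixed params, logLik %.1f, var(patient) %.2f, var(resid) %.2f\n",
                s$model_id, s$fit_objective, s$n_fixed_params,
                s$log_likelihood, s$random_intercept_variance,
                s$residual_variance))
  }
  invisible(x)
}

#' Likelihood-ratio test of two nested mixed models
#'
#' Both models must be ML fits on the same rows with the restricted model's
#' fixed effects nested in the full model's. The statistic is
#' `2 * (logLik_full - logLik_restricted)`, clipped at zero, referred to a
#' chi-square distribution with df equal to the difference in fixed
#' parameter counts.
#'
#' @param restricted,full `lmerMod` ML fits.
#' @return List (`glucirc_lrt`): `chi_square`, `df`, `p_value`,
#'   `n_params` (restricted, full).
#' @export
lrt <- function(restricted, full) {
  if (lme4::isREML(restricted) || lme4::isREML(full)) {
    abort("likelihood-ratio tests require ML fits", class = "glucirc_domain_error")
  }
  if (stats::nobs(restricted) != stats::nobs(full)) {
    abort("models were fitted on different numbers of rows",
          class = "glucirc_domain_error")
  }
  tr <- names(lme4::fixef(restricted))
  tf <- names(lme4::fixef(full))
  if (!all(tr %in% tf) || length(tf) < length(tr)) {
    abort("restricted model is not nested in the full model",
          class = "glucirc_domain_error")
  }
  df <- length(tf) - length(tr)
  chi <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(restricted))))
  p <- if (df == 0) {
    # identical fixed-effect structures: null distribution is a point mass
    if (chi <= 1e-8) 1 else 0
  } else {
    pchisq(chi, df = df, lower.tail = FALSE)
  }
  structure(list(
    chi_square = chi, df = df,
    p_value = p,
    n_params = c(restricted = length(tr), full = length(tf))
  ), class = "glucirc_lrt")
}

#' @export
print.glucirc_lrt <- function(x, ...) {
  cat(sprintf("LRT: chi-square(df = %d) = %.1f, p = %.3g\n", x$df,
              x$chi_square, x$p_value))
  invisible(x)
}

#' Hourly estimated-marginal-means profile from the final model
#'
#' For each hour of day, computes the model-adjusted mean glucose on a
#' reference grid that averages over the levels of every other categorical
#' covariate — with equal weights by default, or weights proportional to
#' the observed level frequencies. Confidence intervals are Wald intervals
#' from the fixed-effect covariance (the random intercept enters at its
#' zero mean).
#'
#' @param fit `lmerMod` for the hour-of-day model (m4).
#' @param weighting `"equal"` (default) or `"frequency"`.
#' @param data Model data; only needed for frequency weighting.
#' @param level Confidence level (default 0.95).
#' @return A `glucirc_emm_profile` tibble: `hour`, `emm`, `se`, `ci_low`,
#'   `ci_high`, with attributes `peak_hour`, `trough_hour`, `amplitude`.
#' @export
emm_profile <- function(fit, weighting = c("equal", "frequency"),
                        data = NULL, level = 0.95) {
  weighting <- match.arg(weighting)
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  fr <- stats::model.frame(fit)
  tt <- stats::delete.response(stats::terms(fit, fixed.only = TRUE))
  factors <- attr(tt, "term.labels")
  xlev <- lapply(factors, function(v) levels(fr[[v]]))
  names(xlev) <- factors
  grid <- expand.grid(xlev, stringsAsFactors = FALSE)
  for (v in factors) grid[[v]] <- factor(grid[[v]], levels = xlev[[v]])
  X <- stats::model.matrix(tt, grid)
  if (!all(colnames(X) %in% names(beta))) {
    # covariate levels unobserved in this (sub)cohort were dropped from the
    # fit; excluding their columns shifts every hour equally, so the shape
    # and peak/trough of the profile are unaffected
    dropped <- setdiff(colnames(X), names(beta))
    warn(paste("profile averages omit unobserved level(s):",
               paste(dropped, collapse = ", ")))
    X <- X[, colnames(X) %in% names(beta), drop = FALSE]
  }
  if (!"hour_factor" %in% factors) {
    abort("emm_profile() needs a model with the hour-of-day factor (m4)",
          class = "glucirc_domain_error")
  }
  hour <- as.integer(sub("h", "", as.character(grid$hour_factor)))
  w <- rep(1, nrow(grid))
  if (weighting == "frequency") {
    if (is.null(data)) data <- fr
    for (v in setdiff(factors, "hour_factor")) {
      freq <- prop.table(table(factor(data[[v]], levels = xlev[[v]])))
      w <- w * as.numeric(freq[as.character(grid[[v]])])
    }
  }
  z <- qnorm(1 - (1 - level) / 2)
  hours <- sort(unique(hour))
  prof <- purrr::map_dfr(hours, function(h) {
    rows_h <- which(hour == h)
    wt <- w[rows_h] / sum(w[rows_h])
    cvec <- colSums(X[rows_h, , drop = FALSE] * wt)
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tibble(hour = h, emm = est, se = se,
           ci_low = est - z * se, ci_high = est + z * se)
  })
  peak <- prof$hour[which.max(prof$emm)]
  trough <- prof$hour[which.min(prof$emm)]
  structure(prof,
            class = c("glucirc_emm_profile", class(prof)),
            peak_hour = peak, trough_hour = trough,
            amplitude = max(prof$emm) - min(prof$emm),
            weighting = weighting)
}

#' Peak/trough summary of an EMM profile
#'
#' @param profile A `glucirc_emm_profile`.
#' @return List: `peak_hour`, `trough_hour`, `amplitude` (mmol/L).
#' @export
emm_summary <- function(profile) {
  list(peak_hour = attr(profile, "peak_hour"),
       trough_hour = attr(profile, "trough_hour"),
       amplitude = attr(profile, "amplitude"))
}

#' @export
print.glucirc_emm_profile <- function(x, ...) {
  cat(sprintf("<emm profile> peak %.2f mmol/L at %02d:00, trough %.2f at %02d:00 (amplitude %.2f)\n",
              max(x$emm), attr(x, "peak_hour"), min(x$emm),
              attr(x, "trough_hour"), attr(x, "amplitude")))
  NextMethod()
}

#' Residual diagnostics for a fitted model
#'
#' Emits conditional residuals and fitted values, a decile-binned
#' residual-vs-fitted table and QQ quantiles, plus residual mean and
#' skewness. No pass/fail verdict: these are report tables.
#'
#' @param fit `lmerMod`.
#' @return List: `residuals`, `fitted`, `resid_fitted` (binned), `qq`,
#'   `mean`, `skewness`.
#' @export
model_diagnostics <- function(fit) {
  r <- resid(fit)
  f <- fitted(fit)
  bins <- cut(f, breaks = quantile(f, probs = seq(0, 1, 0.1)),
              include.lowest = TRUE, labels = FALSE)
  rf <- tibble(bin = bins, fitted = f, residual = r) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(mean_fitted = mean(fitted), mean_residual = mean(residual),
                     sd_residual = sd(residual), n = dplyr::n(),
                     .groups = "drop")
  p <- stats::ppoints(min(length(r), 500))
  qq <- tibble(theoretical = qnorm(p),
               sample = quantile(scale(r), probs = p, names = FALSE))
  skew <- mean((r - mean(r))^3) / sd(r)^3
  list(residuals = r, fitted = f, resid_fitted = rf, qq = qq,
       mean = mean(r), skewness = skew)
}

# ---- gradient-boosted-tree cross-check ----------------------------------

GBM_FEATURES <- c("hour_bin", "age_years", "sex_male", "diabetes_yes",
                  "carb_rate_g_h", "insulin_rate_u_h", "dextrose_rate_g_h",
                  "glucocorticoid_yes")

gbm_feature_matrix <- function(rows) {
  m <- cbind(
    hour_bin = as.numeric(rows$hour_bin),
    age_years = rows$age_years,
    sex_male = as.numeric(rows$sex == "male"),
    diabetes_yes = as.numeric(as.logical(rows$diabetes)),
    carb_rate_g_h = rows$carb_rate_g_h,
    insulin_rate_u_h = rows$insulin_rate_u_h,
    dextrose_rate_g_h = rows$dextrose_rate_g_h,
    glucocorticoid_yes = as.numeric(as.logical(rows$glucocorticoid))
  )
  storage.mode(m) <- "double"
  m
}

#' Gradient-boosted-tree model with per-feature attribution values
#'
#' Fits a gradient-boosted regression-tree model of glucose on the
#' CONTINUOUS covariates (hour of day 0-23, age in years, administration
#' rates) plus the binary ones, with the tuned hyperparameters of the
#' reference analysis (tree depth 5, learning rate 0.1, 150 trees, minimum
#' child weight 5, column and row subsampling 0.75), and computes additive
#' per-feature attribution (SHAP) values for a random sample of
#' measurements.
#'
#' @param rows Analysis-row tibble.
#' @param sample_n Number of rows sampled for the attribution analysis
#'   (default 5000; if fewer rows are available, all are used with a note).
#' @param seed Integer seed for row subsampling and tree randomisation.
#' @param params Optional named list overriding the default xgboost
#'   hyperparameters.
#' @param nrounds Number of boosting rounds (default 150).
#' @param tune If `TRUE`, selects `max_depth` and `min_child_weight` by
#'   5-fold cross-validation grouped by PATIENT (repeated measures must not
#'   straddle folds) before the final fit. Off by default: the fixed tuned
#'   hyperparameters are the reference configuration.
#' @param tune_grid Data frame of candidate `max_depth` /
#'   `min_child_weight` combinations used when `tune = TRUE`.
#' @return A `glucirc_shap_profile`: list with `shap` (per-sampled-row
#'   tibble: `hour`, value and attribution of each feature), `hourly`
#'   (mean hour-of-day attribution by hour), `ranking` (mean absolute
#'   attribution per feature), `base_value`, `model`.
#' @export
fit_gbm_shap <- function(rows, sample_n = 5000, seed = 1L, params = list(),
                         nrounds = 150, tune = FALSE,
                         tune_grid = expand.grid(max_depth = c(3, 5, 7),
                                                 min_child_weight = c(1, 5))) {
  X <- gbm_feature_matrix(rows)
  y <- rows$glucose_mmol_l
  base_params <- list(
    max_depth = 5, eta = 0.1, min_child_weight = 5,
    colsample_bytree = 0.75, subsample = 0.75,
    objective = "reg:squarederror", nthread = 1
  )
  base_params <- utils::modifyList(base_params, params)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  if (isTRUE(tune)) {
    folds_of <- fold_by_patient(rows$patient_id, k = 5)
    scores <- apply(tune_grid, 1, function(g) {
      p <- utils::modifyList(base_params,
                             list(max_depth = g[["max_depth"]],
                                  min_child_weight = g[["min_child_weight"]]))
      rmse <- vapply(1:5, function(k) {
        tr <- folds_of != k
        bst <- xgboost::xgb.train(
          params = p, nrounds = nrounds,
          data = xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
        )
        pred <- predict(bst, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
        sqrt(mean((y[!tr] - pred)^2))
      }, numeric(1))
      mean(rmse)
    })
    best <- tune_grid[which.min(scores), ]
    base_params$max_depth <- best$max_depth
    base_params$min_child_weight <- best$min_child_weight
  }
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  bst <- xgboost::xgb.train(params = base_params, nrounds = nrounds,
                            data = dtrain)
  n <- nrow(X)
  if (n < sample_n) {
    inform(sprintf("only %d rows available; attribution uses all of them", n))
    idx <- seq_len(n)
  } else {
    idx <- sample.int(n, sample_n)
  }
  contrib <- predict(bst, xgboost::xgb.DMatrix(X[idx, , drop = FALSE]),
                     predcontrib = TRUE)
  colnames(contrib) <- c(GBM_FEATURES, "BIAS")
  preds <- predict(bst, xgboost::xgb.DMatrix(X[idx, , drop = FALSE]))
  shap <- tibble::as_tibble(contrib[, GBM_FEATURES, drop = FALSE])
  names(shap) <- paste0("shap_", GBM_FEATURES)
  shap <- dplyr::bind_cols(
    tibble(hour = as.integer(X[idx, "hour_bin"]), prediction = preds),
    tibble::as_tibble(X[idx, , drop = FALSE]), shap
  )
  hourly <- shap |>
    dplyr::group_by(hour) |>
    dplyr::summarise(mean_shap_hour = mean(.data$shap_hour_bin), n = dplyr::n(),
                     .groups = "drop")
  ranking <- tibble(
    feature = GBM_FEATURES,
    mean_abs_shap = vapply(GBM_FEATURES, function(f) {
      mean(abs(shap[[paste0("shap_", f)]]))
    }, numeric(1))
  ) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_shap))
  structure(list(shap = shap, hourly = hourly, ranking = ranking,
                 base_value = unname(contrib[1, "BIAS"]), model = bst,
                 params = base_params),
            class = "glucirc_shap_profile")
}

fold_by_patient <- function(patient_id, k = 5) {
  pats <- unique(patient_id)
  fold_of_pat <- sample(rep(seq_len(k), length.out = length(pats)))
  fold_of_pat[match(patient_id, pats)]
}

#' @export
print.glucirc_shap_profile <- function(x, ...) {
  best <- x$hourly$hour[which.max(x$hourly$mean_shap_hour)]
  worst <- x$hourly$hour[which.min(x$hourly$mean_shap_hour)]
  cat(sprintf("<shap profile> %d rows; hour attribution max at %02d:00, min at %02d:00\n",
              nrow(x$shap), best, worst))
  cat("top features:", paste(head(x$ranking$feature, 4), collapse = ", "), "\n")
  invisible(x)
}
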