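# Synthetic EHR cohort generator with known ground truth.
#
# Emulates the study setting: ICU stays with continuous (interrupted)
# enteral-nutrition runs, glucose sampled non-uniformly over the 24-h day at
# roughly 4 valid measurements per ICU day, insulin in four action classes
# (infusions and pushes), dextrose infusions and pushes, glucocorticoid
# courses, ventilation and sedation-score charting. Glucose values are built
# additively from a fixed-effect truth at the magnitudes of the reference
# analysis (intercept 6.6 mmol/L, diabetes +2.2, ... ; random-intercept
# variance 2.8, residual variance 5.4), a configurable true hour-of-day
# effect, a per-patient random intercept and Gaussian residual noise, so
# every downstream stage can be checked against known parameters.
#
# All event and measurement times are generated on whole minutes.

default_time_effect <- function(amplitude = 0.5, peak_hour = 10) {
  h <- 0:23
  raw <- amplitude * cos(2 * pi * (h - peak_hour) / 24)
  raw - raw[1] # reference hour 0 fixed at 0
}

default_true_coefficients <- function() {
  list(
    intercept = 6.6,
    age = c("55-65" = 0.5, "66-75" = 0.6, ">75" = 0.6),
    sex_male = -0.2,
    diabetes = 2.2,
    carb = c("4.5<x<=6.5" = 0.7, "6.5<x<=8.5" = 1.0, ">8.5" = 1.4),
    insulin = c("0<x<=1.5" = 0.5, "1.5<x<=3" = 0.4, ">3" = -0.2),
    dextrose = c("0<x<=0.5" = 0.1, "0.5<x<=2" = 0.2, ">2" = 0.6),
    glucocorticoid = 1.0
  )
}

default_sampling_intensity <- function() {
  # uniform base plus Gaussian bumps at the routine lab rounds
  h <- 0:23
  w <- rep(1, 24)
  for (centre in c(4, 10, 16, 22)) {
    d <- pmin(abs(h - centre), 24 - abs(h - centre)) # circular distance
    w <- w + 1.0 * exp(-0.5 * (d / 1.0)^2)
  }
  w / sum(w)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the reference study conditions: cohort-level rates
#' (4 valid glucose measurements per ICU day, median length of stay 10
#' days, ~75-80% of the stay on enteral nutrition), fixed effects at the
#' reference magnitudes, random-intercept variance 2.8 and residual
#' variance 5.4 (mmol/L)^2, and a sinusoidal true hour-of-day effect with
#' amplitude 0.5 mmol/L peaking at 10:00 (peak-to-trough 1.0 mmol/L,
#' reference hour 0 anchored at 0).
#'
#' @param n_patients Number of ICU stays to generate (one stay per patient).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param true_time_effect Numeric vector of 24 hourly glucose offsets
#'   (mmol/L, element 1 = hour 0 must be 0), or `NULL` to build a sinusoid
#'   from `time_amplitude`/`peak_hour`.
#' @param time_amplitude,peak_hour Sinusoid parameters used when
#'   `true_time_effect` is `NULL`.
#' @param true_coefficients Named list of fixed-effect truths; partial
#'   overrides are merged over the defaults (see
#'   `glucirc:::default_true_coefficients`).
#' @param random_intercept_sd,residual_sd Standard deviations (mmol/L) of
#'   the per-patient intercept and residual noise; both must be positive.
#' @param sampling_intensity_by_hour 24 non-negative weights for the
#'   hour-of-day of glucose sampling (normalised internally); default is
#'   uniform plus bumps at 04/10/16/22 h.
#' @param samples_per_day Mean glucose samples per ICU day (all of the stay,
#'   before curation).
#' @param fraction_violators Fraction of stays planted to violate one
#'   inclusion criterion (split between short stay, readmission, no
#'   enteral nutrition).
#' @param fraction_invalid Fraction of glucose values pushed above their
#'   sample type's validity limit.
#' @param fraction_simultaneous Fraction of measurements duplicated at the
#'   same resolved time with a different sample type.
#' @param insulin_patient_prob,dextrose_patient_prob,gc_patient_prob
#'   Probability that a patient receives each medication kind at all.
#' @param heavy_insulin_fraction Fraction of insulin-receiving patients
#'   forced into a high daily requirement (> 70 units/day).
#' @param heavy_insulin_amplitude_factor Multiplier on the true hour effect
#'   for the heavy-insulin patients (1 = same 24-h profile as everyone).
#' @param confounding_flags Named logical list enabling diurnal exposure
#'   schedules (`glucocorticoid_schedule`: doses at 08:00;
#'   `dextrose_schedule`: pushes only 06:00-12:00 at elevated rate;
#'   `nutrition_schedule`: higher nutrition rate 06:00-18:00 than at night).
#' @param n_products Number of synthetic nutrition products (carbohydrate
#'   content drawn uniformly from 0.10-0.20 g/mL).
#' @param fraction_unknown_product Fraction of nutrition runs using a
#'   product with unknown carbohydrate content.
#' @return A `glucirc_synth_config` list.
#' @export
synth_config <- function(n_patients = 500,
                         seed = 1L,
                         true_time_effect = NULL,
                         time_amplitude = 0.5,
                         peak_hour = 10,
                         true_coefficients = list(),
                         random_intercept_sd = sqrt(2.8),
                         residual_sd = sqrt(5.4),
                         sampling_intensity_by_hour = default_sampling_intensity(),
                         samples_per_day = 5,
                         fraction_violators = 0.15,
                         fraction_invalid = 0.01,
                         fraction_simultaneous = 0.02,
                         insulin_patient_prob = 0.6,
                         dextrose_patient_prob = 0.5,
                         gc_patient_prob = 0.25,
                         heavy_insulin_fraction = 0,
                         heavy_insulin_amplitude_factor = 1,
                         confounding_flags = list(),
                         n_products = 8,
                         fraction_unknown_product = 0.05) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1) {
    abort("n_patients must be a positive integer", class = "glucirc_config_error")
  }
  if (random_intercept_sd <= 0 || residual_sd <= 0) {
    abort("standard deviations must be positive", class = "glucirc_config_error")
  }
  if (is.null(true_time_effect)) {
    true_time_effect <- default_time_effect(time_amplitude, peak_hour)
  }
  if (length(true_time_effect) != 24 || abs(true_time_effect[1]) > 1e-12) {
    abort("true_time_effect must have 24 elements with element 1 (hour 0) = 0",
          class = "glucirc_config_error")
  }
  if (length(sampling_intensity_by_hour) != 24 ||
      any(sampling_intensity_by_hour < 0) || sum(sampling_intensity_by_hour) <= 0) {
    abort("sampling_intensity_by_hour must be 24 non-negative weights",
          class = "glucirc_config_error")
  }
  flags <- utils::modifyList(
    list(glucocorticoid_schedule = FALSE, dextrose_schedule = FALSE,
         nutrition_schedule = FALSE),
    as.list(confounding_flags)
  )
  coefs <- utils::modifyList(default_true_coefficients(),
                             as.list(true_coefficients))
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    true_time_effect = as.numeric(true_time_effect),
    true_coefficients = coefs,
    random_intercept_sd = random_intercept_sd, residual_sd = residual_sd,
    sampling_intensity_by_hour = sampling_intensity_by_hour / sum(sampling_intensity_by_hour),
    samples_per_day = samples_per_day,
    fraction_violators = fraction_violators,
    fraction_invalid = fraction_invalid,
    fraction_simultaneous = fraction_simultaneous,
    insulin_patient_prob = insulin_patient_prob,
    dextrose_patient_prob = dextrose_patient_prob,
    gc_patient_prob = gc_patient_prob,
    heavy_insulin_fraction = heavy_insulin_fraction,
    heavy_insulin_amplitude_factor = heavy_insulin_amplitude_factor,
    confounding_flags = flags,
    n_products = as.integer(n_products),
    fraction_unknown_product = fraction_unknown_product
  ), class = "glucirc_synth_config")
}

# Round a POSIXct down to the whole minute.
floor_minute <- function(x) {
  as.POSIXct(floor(as.numeric(x) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

# Piecewise nutrition runs for one stay. Returns start/end (minutes),
# product index and rate. Under the diurnal nutrition schedule runs are
# split at 06:00/18:00 with a higher daytime rate.
make_nutrition_runs <- function(admit, discharge, config, products) {
  runs_s <- c(); runs_e <- c()
  t <- admit + round(runif(1, 0, 12) * 60) * 60
  while (t < discharge) {
    len_h <- rlnorm(1, log(24), 0.5)
    e <- min(t + round(len_h * 60) * 60, discharge)
    if (e > t) { runs_s <- c(runs_s, as.numeric(t)); runs_e <- c(runs_e, as.numeric(e)) }
    gap_h <- rlnorm(1, log(6), 0.6)
    t <- e + round(gap_h * 60) * 60
  }
  if (length(runs_s) == 0) return(NULL)
  starts <- as.POSIXct(runs_s, origin = "1970-01-01", tz = "UTC")
  ends <- as.POSIXct(runs_e, origin = "1970-01-01", tz = "UTC")
  n <- length(starts)
  prod_idx <- sample.int(nrow(products), n, replace = TRUE,
                         prob = products$use_weight)
  if (!config$confounding_flags$nutrition_schedule) {
    tibble(start_time = starts, end_time = ends,
           product_id = products$product_id[prod_idx],
           rate = round(runif(n, 25, 75), 1))
  } else {
    # split at 06:00 and 18:00 boundaries; day rate high, night rate low
    out_s <- c(); out_e <- c(); out_p <- c(); out_r <- c()
    for (i in seq_len(n)) {
      day0 <- as.numeric(trunc(starts[i], "days"))
      cuts <- sort(unique(c(
        as.numeric(starts[i]), as.numeric(ends[i]),
        day0 + rep(c(6, 18) * 3600, each = 15) + rep(0:14, times = 2) * 86400
      )))
      cuts <- cuts[cuts >= as.numeric(starts[i]) & cuts <= as.numeric(ends[i])]
      for (j in seq_len(length(cuts) - 1)) {
        mid_h <- as.integer(format(as.POSIXct(cuts[j], origin = "1970-01-01",
                                              tz = "UTC"), "%H", tz = "UTC"))
        out_s <- c(out_s, cuts[j]); out_e <- c(out_e, cuts[j + 1])
        out_p <- c(out_p, products$product_id[prod_idx[i]])
        out_r <- c(out_r, if (mid_h >= 6 && mid_h < 18) 65 else 30)
      }
    }
    tibble(start_time = as.POSIXct(out_s, origin = "1970-01-01", tz = "UTC"),
           end_time = as.POSIXct(out_e, origin = "1970-01-01", tz = "UTC"),
           product_id = out_p, rate = out_r)
  }
}

#' Generate a synthetic ICU cohort with known ground truth
#'
#' Deterministic given `config$seed` (the caller's RNG state is preserved).
#' A configurable fraction of stays is planted to violate one inclusion
#' criterion (short stay, readmission, or no enteral nutrition), a fraction
#' of glucose values exceeds the validity limit of its sample type, and a
#' fraction of measurements is duplicated at the same instant with a
#' different sample type, so that every curation rule is exercised.
#'
#' @param config A [synth_config()].
#' @return List with `tables` (a validated `glucirc_bundle`) and `truth`
#'   (list: `patient_intercepts`, `coefficients`, `time_effect`,
#'   `planted_violations`, `heavy_insulin_patients`, `config`).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "glucirc_synth_config")) {
    abort("config must be created with synth_config()", class = "glucirc_config_error")
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  cf <- config$true_coefficients
  n <- config$n_patients
  flags <- config$confounding_flags
  if (flags$glucocorticoid_schedule && config$gc_patient_prob <= 0) {
    abort("glucocorticoid_schedule flag set but gc_patient_prob is 0",
          class = "glucirc_config_error")
  }
  if (flags$dextrose_schedule && config$dextrose_patient_prob <= 0) {
    abort("dextrose_schedule flag set but dextrose_patient_prob is 0",
          class = "glucirc_config_error")
  }

  ids <- sprintf("s%05d", seq_len(n))
  pids <- sprintf("p%05d", seq_len(n))

  # planted inclusion-criterion violations
  n_viol <- round(config$fraction_violators * n)
  viol_idx <- if (n_viol > 0) sample.int(n, n_viol) else integer(0)
  viol_type <- if (n_viol > 0) {
    sample(c("los_lt_4_days", "readmission", "no_enteral_nutrition"),
           n_viol, replace = TRUE)
  } else character(0)
  violation <- rep(NA_character_, n)
  violation[viol_idx] <- viol_type

  base <- parse_timestamp("2120-01-01T00:00:00")
  admit <- floor_minute(base + runif(n, 0, 365) * 86400)
  los <- pmin(pmax(rlnorm(n, log(10), 0.55), 4.05), 45)
  los[which(violation == "los_lt_4_days")] <-
    runif(sum(violation == "los_lt_4_days", na.rm = TRUE), 1, 3.9)
  discharge <- floor_minute(admit + los * 86400)

  age <- pmin(pmax(rnorm(n, 66, 14), 18), 95)
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.57, 0.43))
  diabetes <- runif(n) < 0.31
  race <- sample(c("white", "black", "hispanic", "asian", "other", "unknown"),
                 n, replace = TRUE, prob = c(0.61, 0.10, 0.04, 0.03, 0.04, 0.18))
  admission_type <- sample(c("elective", "emergency"), n, replace = TRUE,
                           prob = c(0.07, 0.93))
  sofa <- rpois(n, 8); sofa[runif(n) < 0.05] <- NA
  oasis <- pmax(10L, as.integer(round(rnorm(n, 40, 8)))); oasis[runif(n) < 0.05] <- NA
  mortality <- runif(n) < 0.28

  stays <- tibble(
    stay_id = ids, patient_id = pids,
    admit_time = admit, discharge_time = discharge,
    is_readmission = !is.na(violation) & violation == "readmission",
    age_years = round(age, 1), sex = sex, diabetes = diabetes, race = race,
    admission_type = admission_type, sofa_admission = sofa, oasis = oasis,
    in_hospital_mortality = mortality
  )

  products <- tibble(
    product_id = sprintf("prod%02d", seq_len(config$n_products)),
    carb_g_ml = round(runif(config$n_products, 0.10, 0.20), 3),
    use_weight = rep(1, config$n_products)
  )
  if (config$fraction_unknown_product > 0) {
    products <- dplyr::bind_rows(products, tibble(
      product_id = "prod_unknown", carb_g_ml = NA_real_,
      use_weight = config$fraction_unknown_product * config$n_products /
        max(1 - config$fraction_unknown_product, 1e-9)
    ))
  }

  # per-patient medication propensities
  uses_insulin <- runif(n) < config$insulin_patient_prob
  heavy <- rep(FALSE, n)
  if (config$heavy_insulin_fraction > 0) {
    cand <- which(uses_insulin & is.na(violation))
    n_heavy <- round(config$heavy_insulin_fraction * length(cand))
    heavy[sample(cand, min(n_heavy, length(cand)))] <- TRUE
  }
  daily_insulin <- ifelse(heavy, runif(n, 90, 150), rlnorm(n, log(30), 0.8))
  uses_dextrose <- runif(n) < config$dextrose_patient_prob
  uses_gc <- runif(n) < config$gc_patient_prob

  b <- rnorm(n, 0, config$random_intercept_sd)

  nut_list <- vector("list", n)
  med_list <- vector("list", n)
  vent_list <- vector("list", n)
  rass_list <- vector("list", n)

  for (i in seq_len(n)) {
    a <- admit[i]; d <- discharge[i]; stay_days <- los[i]
    if (is.na(violation[i]) || violation[i] != "no_enteral_nutrition") {
      nr <- make_nutrition_runs(a, d, config, products)
      if (!is.null(nr)) { nr$stay_id <- ids[i]; nut_list[[i]] <- nr }
    }
    med <- list()
    if (uses_insulin[i]) {
      days <- seq_len(max(1, floor(stay_days)))
      # one infusion per day carrying ~70% of the daily dose
      L <- runif(length(days), 4, 12)
      st <- a + round((days - 1) * 1440 + runif(length(days), 0, 12 * 60)) * 60
      en <- pmin(st + round(L * 60) * 60, d)
      ok <- en > st & st < d
      if (any(ok)) {
        med$ins_inf <- tibble(
          stay_id = ids[i], kind = "insulin", subtype = "short",
          start_time = st[ok], end_time = en[ok],
          rate = round(0.7 * daily_insulin[i] / L[ok], 2), amount = NA_real_
        )
      }
      n_push <- rpois(1, 0.3 * daily_insulin[i] / 6 * stay_days)
      if (n_push > 0) {
        pt <- a + round(runif(n_push, 0, stay_days * 1440)) * 60
        pt <- pt[pt < d]
        if (length(pt) > 0) {
          med$ins_push <- tibble(
            stay_id = ids[i], kind = "insulin",
            subtype = sample(INSULIN_CLASSES, length(pt), replace = TRUE),
            start_time = pt, end_time = pt,
            rate = NA_real_, amount = round(runif(length(pt), 4, 10), 1)
          )
        }
      }
    }
    if (uses_dextrose[i]) {
      push_per_day <- if (flags$dextrose_schedule) 1.5 else 0.3
      n_push <- rpois(1, push_per_day * stay_days)
      if (n_push > 0) {
        if (flags$dextrose_schedule) {
          day_off <- floor(runif(n_push, 0, ceiling(stay_days)))
          day0 <- as.numeric(trunc(a, "days"))
          pt <- as.POSIXct(day0 + day_off * 86400 +
                             round(runif(n_push, 6 * 60, 12 * 60 - 1)) * 60,
                           origin = "1970-01-01", tz = "UTC")
        } else {
          pt <- a + round(runif(n_push, 0, stay_days * 1440)) * 60
        }
        pt <- pt[pt >= a & pt < d]
        if (length(pt) > 0) {
          med$dex_push <- tibble(
            stay_id = ids[i], kind = "dextrose", subtype = "push",
            start_time = pt, end_time = pt,
            rate = NA_real_, amount = round(runif(length(pt), 5, 25), 1)
          )
        }
      }
      if (!flags$dextrose_schedule) {
        # maintenance dextrose-containing fluids: a few multi-hour runs
        n_inf <- sample(1:3, 1)
        st <- a + round(runif(n_inf, 0, stay_days * 1440 * 0.8)) * 60
        en <- pmin(st + round(runif(n_inf, 12, 48) * 60) * 60, d)
        ok <- en > st
        if (any(ok)) {
          med$dex_inf <- tibble(
            stay_id = ids[i], kind = "dextrose", subtype = "infusion",
            start_time = st[ok], end_time = en[ok],
            rate = round(runif(sum(ok), 0.1, 3), 2), amount = NA_real_
          )
        }
      }
    }
    if (uses_gc[i]) {
      course_days <- sample(1:5, 1)
      first_day <- floor(runif(1, 0, max(stay_days - 1, 0.5)))
      day0 <- as.numeric(trunc(a, "days"))
      dose_hour_min <- if (flags$glucocorticoid_schedule) {
        rep(8 * 60, course_days)
      } else {
        round(runif(course_days, 0, 1439))
      }
      pt <- as.POSIXct(day0 + (first_day + seq_len(course_days) - 1) * 86400 +
                         dose_hour_min * 60, origin = "1970-01-01", tz = "UTC")
      pt <- pt[pt >= a & pt < d]
      if (length(pt) > 0) {
        med$gc <- tibble(
          stay_id = ids[i], kind = "glucocorticoid", subtype = NA_character_,
          start_time = pt, end_time = pt, rate = NA_real_, amount = NA_real_
        )
      }
    }
    if (length(med) > 0) med_list[[i]] <- dplyr::bind_rows(med)

    v0 <- sample(VENT_STATES, 1, prob = c(0.90, 0.087, 0.013))
    vt <- a
    vs <- v0
    if (v0 == "invasive" && stay_days > 5 && runif(1) < 0.6) {
      vt <- c(vt, a + round(runif(1, 0.4, 0.8) * stay_days * 1440) * 60)
      vs <- c(vs, sample(c("non_invasive", "none"), 1))
    }
    vent_list[[i]] <- tibble(stay_id = ids[i], time = vt, state = vs)

    n_rass <- max(1, round(stay_days * 6))
    rt <- a + round(sort(runif(n_rass, 0, stay_days * 1440))) * 60
    rt <- rt[rt < d]
    mu <- if (v0 == "invasive") -2 else 0
    rv <- pmin(pmax(as.integer(round(rnorm(length(rt), mu, 1.5))), -5L), 4L)
    if (length(rt) > 0) {
      rass_list[[i]] <- tibble(stay_id = ids[i], time = rt, rass = rv)
    }
  }

  nutrition <- dplyr::bind_rows(nut_list)
  medication <- dplyr::bind_rows(med_list)
  ventilation <- dplyr::bind_rows(vent_list)
  rass_tbl <- dplyr::bind_rows(rass_list)

  # ---- glucose sampling -------------------------------------------------
  n_samp <- rpois(n, config$samples_per_day * los)
  n_samp[n_samp < 1] <- 1
  stay_of <- rep(seq_len(n), n_samp)
  m <- length(stay_of)
  day_off <- floor(runif(m) * (los[stay_of] + 1))
  hour <- sample(0:23, m, replace = TRUE, prob = config$sampling_intensity_by_hour)
  minute <- sample(0:59, m, replace = TRUE)
  day0 <- trunc(admit[stay_of], "days")
  chart <- day0 + day_off * 86400 + hour * 3600 + minute * 60
  keep <- chart >= admit[stay_of] & chart < discharge[stay_of]
  stay_of <- stay_of[keep]; chart <- chart[keep]
  # every stay keeps at least one in-stay measurement, so only the planted
  # violators can fail the has-glucose inclusion criterion
  empty <- setdiff(seq_len(n), unique(stay_of))
  if (length(empty) > 0) {
    stay_of <- c(stay_of, empty)
    chart <- c(chart, floor_minute(admit[empty] + los[empty] * 43200))
  }
  m <- length(stay_of)
  stype <- sample(SAMPLE_TYPES, m, replace = TRUE, prob = c(0.30, 0.15, 0.55))
  store <- chart + round(runif(m, -10, 60)) * 60
  store[runif(m) < 0.10] <- NA

  # inject simultaneous duplicate measurements (same resolved instant,
  # different sample type)
  n_dup <- round(config$fraction_simultaneous * m)
  if (n_dup > 0) {
    di <- sample.int(m, n_dup)
    other <- vapply(stype[di], function(s) sample(setdiff(SAMPLE_TYPES, s), 1),
                    character(1))
    stay_of <- c(stay_of, stay_of[di])
    chart <- c(chart, chart[di])
    store <- c(store, store[di])
    stype <- c(stype, other)
    m <- length(stay_of)
  }

  glucose <- tibble(
    stay_id = ids[stay_of],
    chart_time = chart, store_time = store,
    value_mmol_l = NA_real_, sample_type = stype
  )
  glucose <- resolve_glucose_times(glucose)

  # true exposure covariates at the resolved time, via the same window
  # rules the analysis applies
  med2 <- medication
  nut2 <- nutrition
  if (nrow(nut2) > 0) {
    nut2$kind <- "enteral_nutrition"; nut2$subtype <- nut2$product_id
    nut2$amount <- NA_real_
  }
  events <- dplyr::bind_rows(
    if (nrow(med2) > 0) med2[, c("stay_id", "kind", "subtype", "start_time",
                                 "end_time", "rate", "amount")],
    if (nrow(nut2) > 0) nut2[, c("stay_id", "kind", "subtype", "start_time",
                                 "end_time", "rate", "amount")]
  )
  if (!is.null(events) && nrow(events) > 0) {
    win <- effective_rate(correct_window(events))
    win$product_id <- ifelse(win$kind == "enteral_nutrition", win$subtype,
                             NA_character_)
    win <- carb_rate(win, products)
    win$carb_rate_g_h[win$kind != "enteral_nutrition"] <- NA_real_
    glucose <- match_exposures(glucose, win)
  } else {
    glucose$insulin_rate_u_h <- 0
    glucose$dextrose_rate_g_h <- 0
    glucose$carb_rate_g_h <- 0
    glucose$glucocorticoid <- FALSE
  }
  glucose$carb_rate_g_h[is.na(glucose$carb_rate_g_h)] <- 0

  sidx <- match(glucose$stay_id, ids)
  eff <- function(f, coefv) {
    l <- as.character(f)
    out <- rep(0, length(l))
    hit <- l %in% names(coefv)
    out[hit] <- coefv[l[hit]]
    out
  }
  amp_factor <- ifelse(heavy[sidx], config$heavy_insulin_amplitude_factor, 1)
  mu <- cf$intercept +
    eff(categorise_age(stays$age_years[sidx]), cf$age) +
    ifelse(stays$sex[sidx] == "male", cf$sex_male, 0) +
    ifelse(stays$diabetes[sidx], cf$diabetes, 0) +
    eff(categorise_carb(glucose$carb_rate_g_h), cf$carb) +
    eff(categorise_insulin(glucose$insulin_rate_u_h), cf$insulin) +
    eff(categorise_dextrose(glucose$dextrose_rate_g_h), cf$dextrose) +
    ifelse(glucose$glucocorticoid, cf$glucocorticoid, 0) +
    amp_factor * config$true_time_effect[glucose$hour_bin + 1] +
    b[sidx]
  value <- mu + rnorm(nrow(glucose), 0, config$residual_sd)
  value <- pmax(round(value, 1), 0.3)

  # push a fraction above the validity limit of their sample type
  inval <- runif(nrow(glucose)) < config$fraction_invalid
  lim <- glucose_validity_limits[glucose$sample_type]
  value[inval] <- round(lim[inval] + runif(sum(inval), 0.2, 20), 1)
  glucose$value_mmol_l <- value

  tables <- list(
    stays = stays,
    glucose_events = glucose[, c("stay_id", "chart_time", "store_time",
                                 "value_mmol_l", "sample_type")],
    nutrition_events = if (nrow(nutrition) > 0) {
      nutrition[, c("stay_id", "product_id", "start_time", "end_time", "rate")]
    } else NULL,
    medication_events = if (nrow(medication) > 0) medication else NULL,
    ventilation_events = ventilation,
    rass_events = rass_tbl,
    products = products[, c("product_id", "carb_g_ml")]
  )
  bundle <- validate_bundle(tables[!vapply(tables, is.null, logical(1))])
  if (nrow(bundle$row_errors) > 0) {
    abort("internal error: generated tables failed validation")
  }
  truth <- list(
    patient_intercepts = setNames(b, pids),
    coefficients = cf,
    time_effect = config$true_time_effect,
    planted_violations = tibble(stay_id = ids[!is.na(violation)],
                                violation = violation[!is.na(violation)]),
    heavy_insulin_patients = pids[heavy],
    config = config
  )
  list(tables = bundle, truth = truth)
}

#' Generate a confounded cohort: diurnal exposures, zero true time effect
#'
#' Schedules exposures diurnally (per the enabled `confounding_flags`) while
#' forcing the true hour-of-day effect to zero, so the crude hourly mean
#' shows 24-h structure that a correctly adjusted model must remove.
#'
#' @param config A [synth_config()] with at least one confounding flag set;
#'   its `true_time_effect` is replaced by zeros.
#' @return Same shape as [generate_cohort()].
#' @export
generate_confounded_cohort <- function(config) {
  if (!inherits(config, "glucirc_synth_config")) {
    abort("config must be created with synth_config()", class = "glucirc_config_error")
  }
  if (!any(unlist(config$confounding_flags))) {
    abort("at least one confounding flag must be set",
          class = "glucirc_config_error")
  }
  config$true_time_effect <- rep(0, 24)
  generate_cohort(config)
}
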