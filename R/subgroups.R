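# Subgroup construction and per-subgroup hour-of-day profiles.
#
# Each subgroup axis partitions the analysis rows (or stays); within each
# level the full hour-of-day model (same specification as m4) is refitted
# and profiled. Levels with unpopulated hour bins or fewer than two
# patients are reported as skipped, never silently dropped.

INSULIN_TIERS <- c("none", "low", "mid", "high")

#' Assign stay-level insulin-requirement tiers
#'
#' Computes each stay's average daily insulin dose (total units delivered
#' over the stay divided by length of stay in days) and assigns tiers:
#' `none` (no insulin at any point), `low` (0 < x <= 35 units/day),
#' `mid` (35 < x <= 70), `high` (> 70).
#'
#' @param stays Stays tibble.
#' @param medication Medication-events tibble (the full stay record).
#' @return Tibble: `stay_id`, `total_units`, `los_days`, `units_per_day`,
#'   `tier` (factor).
#' @export
assign_insulin_tier <- function(stays, medication) {
  ins <- medication[medication$kind == "insulin", , drop = FALSE]
  units <- rep(0, nrow(stays))
  if (nrow(ins) > 0) {
    dur_h <- diff_hours(ins$end_time, ins$start_time)
    ev_units <- ifelse(!is.na(ins$amount), ins$amount, ins$rate * dur_h)
    if (any(ev_units < 0, na.rm = TRUE)) {
      abort("negative insulin totals", class = "glucirc_domain_error")
    }
    agg <- tapply(ev_units, ins$stay_id, sum)
    idx <- match(stays$stay_id, names(agg))
    units[!is.na(idx)] <- agg[idx[!is.na(idx)]]
  }
  los <- diff_days(stays$discharge_time, stays$admit_time)
  upd <- units / los
  tier <- ifelse(units == 0, "none",
          ifelse(upd <= 35, "low",
          ifelse(upd <= 70, "mid", "high")))
  tibble(stay_id = stays$stay_id, total_units = units, los_days = los,
         units_per_day = upd, tier = factor(tier, levels = INSULIN_TIERS))
}

#' Default subgroup specifications
#'
#' Row-level predicates defining the sensitivity-analysis subgroups:
#' ventilation mode, in-hospital mortality, sedation depth (RASS <= -2 as
#' the sedation proxy), days in ICU (bins 1-3 / 4-7 / >= 8, a convention),
#' sample type, sampling frequency (time to next sample <= 2 h / 2-6 h /
#' > 6 h, a convention), and stay-level insulin-requirement tier.
#'
#' @param stays Stays tibble (for mortality and insulin tiers).
#' @param medication Medication-events tibble (for insulin tiers).
#' @param icu_day_breaks,ttn_breaks Override the convention bin edges.
#' @return Named list of subgroup specs; each is a named list of predicate
#'   functions over the analysis rows.
#' @export
subgroup_specs <- function(stays = NULL, medication = NULL,
                           icu_day_breaks = c(3, 7),
                           ttn_breaks = c(2, 6)) {
  specs <- list(
    ventilation = list(
      invasive = function(r) r$ventilation == "invasive",
      non_invasive = function(r) r$ventilation == "non_invasive",
      none = function(r) r$ventilation == "none"
    ),
    mortality = NULL, # filled below if stays given
    rass = list(
      sedated = function(r) !is.na(r$rass) & r$rass <= -2,
      not_sedated = function(r) !is.na(r$rass) & r$rass > -2
    ),
    icu_day = list(
      day_1_3 = function(r) r$days_since_admission < icu_day_breaks[1],
      day_4_7 = function(r) r$days_since_admission >= icu_day_breaks[1] &
        r$days_since_admission < icu_day_breaks[2],
      day_8_plus = function(r) r$days_since_admission >= icu_day_breaks[2]
    ),
    sample_type = list(
      capillary = function(r) r$sample_type == "capillary",
      laboratory = function(r) r$sample_type %in% c("whole_blood", "serum")
    ),
    sampling_frequency = list(
      le_2h = function(r) !is.na(r$time_to_next_sample_h) &
        r$time_to_next_sample_h <= ttn_breaks[1],
      h2_6 = function(r) !is.na(r$time_to_next_sample_h) &
        r$time_to_next_sample_h > ttn_breaks[1] &
        r$time_to_next_sample_h <= ttn_breaks[2],
      gt_6h = function(r) !is.na(r$time_to_next_sample_h) &
        r$time_to_next_sample_h > ttn_breaks[2]
    )
  )
  if (!is.null(stays)) {
    dead <- stays$stay_id[stays$in_hospital_mortality]
    alive <- stays$stay_id[!stays$in_hospital_mortality]
    specs$mortality <- list(
      died = function(r) r$stay_id %in% dead,
      survived = function(r) r$stay_id %in% alive
    )
    if (!is.null(medication)) {
      tiers <- assign_insulin_tier(stays, medication)
      specs$insulin_requirement <- lapply(INSULIN_TIERS, function(tn) {
        sids <- tiers$stay_id[tiers$tier == tn]
        function(r) r$stay_id %in% sids
      })
      names(specs$insulin_requirement) <- INSULIN_TIERS
    }
  } else {
    specs$mortality <- NULL
  }
  specs[!vapply(specs, is.null, logical(1))]
}

# The hour-of-day model refitted inside one subgroup. Covariates that are
# constant within the subgroup (e.g. insulin band in the never-insulin
# tier) carry no information there and are dropped from the formula;
# factor levels are restricted to those observed so the profile averages
# over the subgroup's own covariate space.
fit_subgroup_m4 <- function(rows, objective = "ML") {
  d <- droplevels(prepare_model_data(rows))
  covs <- c("age_cat", "sex", "diabetes", "carb_cat", "insulin_cat",
            "dextrose_cat", "glucocorticoid")
  keep <- covs[vapply(covs, function(v) nlevels(d[[v]]) >= 2, logical(1))]
  f <- as.formula(paste(
    "glucose_mmol_l ~",
    paste(c("1", keep, "hour_factor", "(1 | patient_id)"), collapse = " + ")
  ))
  lme4::lmer(f, data = d, REML = identical(objective, "REML"),
             control = lme4::lmerControl(calc.derivs = FALSE,
                                         check.conv.singular = "ignore"))
}

#' Fit the hour-of-day model within each subgroup
#'
#' For each level of each subgroup axis, refits the full hour-of-day model
#' (same specification as m4) on the level's rows and computes the hourly
#' estimated-marginal-means profile. Levels that cannot support the model
#' (fewer than 2 patients, an unpopulated hour bin, or a covariate with a
#' single level) are recorded as skipped with the reason.
#'
#' @param rows Analysis-row tibble.
#' @param specs Subgroup specification list ([subgroup_specs()]).
#' @param objective `"ML"` (default, matching the main profile) or `"REML"`.
#' @return A `glucirc_subgroup_result`: tibble `profiles` (subgroup, level,
#'   hour, emm, ci bounds), list `emm` of profiles, tibble `counts`
#'   (rows/patients per level), tibble `skipped` (level, reason).
#' @export
run_subgroup_analysis <- function(rows, specs, objective = "ML") {
  counts <- list(); skipped <- list(); profs <- list(); prof_rows <- list()
  for (axis in names(specs)) {
    for (lvl in names(specs[[axis]])) {
      sel <- specs[[axis]][[lvl]](rows)
      sel[is.na(sel)] <- FALSE
      sub <- rows[sel, , drop = FALSE]
      key <- paste(axis, lvl, sep = ".")
      counts[[key]] <- tibble(subgroup = axis, level = lvl,
                              n_rows = nrow(sub),
                              n_patients = length(unique(sub$patient_id)))
      reason <- NULL
      if (length(unique(sub$patient_id)) < 2) {
        reason <- "fewer than 2 patients"
      } else if (length(unique(sub$hour_bin)) < 24) {
        reason <- "unpopulated hour bins"
      }
      if (!is.null(reason)) {
        skipped[[key]] <- tibble(subgroup = axis, level = lvl, reason = reason)
        next
      }
      fit <- tryCatch(
        suppressWarnings(fit_subgroup_m4(sub, objective)),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        skipped[[key]] <- tibble(subgroup = axis, level = lvl,
                                 reason = conditionMessage(fit))
        next
      }
      prof <- emm_profile(fit)
      profs[[key]] <- prof
      prof_rows[[key]] <- dplyr::mutate(tibble::as_tibble(prof),
                                        subgroup = axis, level = lvl,
                                        .before = 1)
    }
  }
  structure(list(
    profiles = dplyr::bind_rows(prof_rows),
    emm = profs,
    counts = dplyr::bind_rows(counts),
    skipped = dplyr::bind_rows(skipped)
  ), class = "glucirc_subgroup_result")
}

#' @export
print.glucirc_subgroup_result <- function(x, ...) {
  cat("<subgroup analysis>\n")
  print(as.data.frame(x$counts), row.names = FALSE)
  if (nrow(x$skipped) > 0) {
    cat("skipped:\n")
    print(as.data.frame(x$skipped), row.names = FALSE)
  }
  invisible(x)
}
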