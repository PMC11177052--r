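# Pharmacokinetic effect-window correction and temporal matching of
# exposures to glucose measurements.
#
# Window conventions: all effect windows are half-open [start, end): a
# measurement at the exact window start matches, one at the exact end does
# not. Concurrent windows of the same exposure kind sum their effective
# rates (additive administration).

INSULIN_EXTENSION_H <- c(rapid = 2, short = 4, intermediate = 10, long = 12)
INSULIN_START_SHIFT_H <- 0.5
GLUCOCORTICOID_EXTENSION_H <- 24
DEXTROSE_PUSH_WINDOW_MIN <- 10

#' Correct exposure start/end times into pharmacokinetic effect windows
#'
#' Applies fixed corrections reflecting onset and persistence of action:
#' insulin windows start 0.5 h after the administration start and extend
#' beyond the administration end by 2, 4, 10 or 12 h for rapid-, short-,
#' intermediate- and long-acting insulin respectively; glucocorticoid
#' windows extend 24 h beyond the administration end; dextrose pushes get a
#' 10-minute window from the push time; dextrose infusions and enteral
#' nutrition keep their recorded interval.
#'
#' @param events Tibble of exposure events with columns `stay_id`, `kind`,
#'   `subtype`, `start_time`, `end_time`, `rate`, `amount`.
#' @return The events tibble with `window_start` and `window_end` columns
#'   added.
#' @export
#' @examples
#' e <- tibble::tibble(
#'   stay_id = "s1", kind = "insulin", subtype = "short",
#'   start_time = parse_timestamp("2120-01-01T08:00:00"),
#'   end_time = parse_timestamp("2120-01-01T09:00:00"),
#'   rate = 2, amount = NA_real_
#' )
#' correct_window(e)[, c("window_start", "window_end")]
correct_window <- function(events) {
  n <- nrow(events)
  ws <- events$start_time
  we <- events$end_time
  is_insulin <- events$kind == "insulin"
  if (any(is_insulin & !(events$subtype %in% INSULIN_CLASSES))) {
    abort("insulin event without action class (rapid/short/intermediate/long)",
          class = "glucirc_domain_error")
  }
  ws[is_insulin] <- events$start_time[is_insulin] + INSULIN_START_SHIFT_H * 3600
  we[is_insulin] <- events$end_time[is_insulin] +
    INSULIN_EXTENSION_H[events$subtype[is_insulin]] * 3600
  is_gc <- events$kind == "glucocorticoid"
  we[is_gc] <- events$end_time[is_gc] + GLUCOCORTICOID_EXTENSION_H * 3600
  is_push <- events$kind == "dextrose" & events$subtype == "push"
  we[is_push] <- events$start_time[is_push] + DEXTROSE_PUSH_WINDOW_MIN * 60
  events$window_start <- ws
  events$window_end <- we
  events
}

#' Effective administration rate over a corrected effect window
#'
#' Infusions keep their recorded rate, held constant over the corrected
#' window. Discrete pushes/boluses are converted to a rate by dividing the
#' administered amount by the corrected window duration. Glucocorticoids
#' are a presence flag and get no rate (`NA`).
#'
#' @param events Tibble with corrected windows ([correct_window()]).
#' @return The tibble with an `effective_rate` column (units/h for insulin,
#'   g/h for dextrose, mL/h for nutrition, `NA` for glucocorticoids).
#' @export
effective_rate <- function(events) {
  dur_h <- diff_hours(events$window_end, events$window_start)
  has_amount <- !is.na(events$amount)
  if (any(has_amount & dur_h <= 0)) {
    abort("zero-duration window with a nonzero administered amount",
          class = "glucirc_domain_error")
  }
  er <- events$rate
  er[has_amount] <- events$amount[has_amount] / dur_h[has_amount]
  er[events$kind == "glucocorticoid"] <- NA_real_
  events$effective_rate <- er
  events
}

#' Carbohydrate administration rate of nutrition events (g/h)
#'
#' Multiplies the hourly nutrition rate (mL/h) by the carbohydrate content
#' of the administered product (g/mL). Products absent from the lookup, or
#' present with unknown content, yield `NA` — measurements matched only to
#' such events are removed upstream during curation.
#'
#' @param nutrition Nutrition-events tibble (`product_id`, `rate`).
#' @param products Product lookup (`product_id`, `carb_g_ml`).
#' @return The nutrition tibble with a `carb_rate_g_h` column.
#' @export
carb_rate <- function(nutrition, products) {
  content <- products$carb_g_ml[match(nutrition$product_id, products$product_id)]
  nutrition$carb_rate_g_h <- nutrition$rate * content
  nutrition
}

# ---- interval-join primitives -------------------------------------------

# Sum, at each query time, the rates of the intervals (of one stay) that
# cover it under the half-open [start, end) convention. Sweep-line: the
# active-rate sum at t equals (sum of rates with start <= t) - (sum of
# rates with end <= t), evaluated by findInterval on the sorted boundary
# vectors.
rate_sum_at <- function(q, starts, ends, rates) {
  if (length(starts) == 0) return(numeric(length(q)))
  os <- order(starts)
  oe <- order(ends)
  cs <- cumsum(rates[os])
  ce <- cumsum(rates[oe])
  i_s <- findInterval(as.numeric(q), as.numeric(starts)[os])
  i_e <- findInterval(as.numeric(q), as.numeric(ends)[oe])
  started <- ifelse(i_s == 0, 0, cs[pmax(i_s, 1)])
  ended <- ifelse(i_e == 0, 0, ce[pmax(i_e, 1)])
  started - ended
}

# Per-stay grouped version over whole tables.
interval_rate_sum <- function(q_stay, q_time, iv_stay, iv_start, iv_end, iv_rate) {
  out <- numeric(length(q_time))
  if (length(iv_stay) == 0 || length(q_time) == 0) return(out)
  q_groups <- split(seq_along(q_time), q_stay)
  iv_groups <- split(seq_along(iv_stay), iv_stay)
  for (sid in names(q_groups)) {
    qi <- q_groups[[sid]]
    ii <- iv_groups[[sid]]
    if (is.null(ii)) next
    out[qi] <- rate_sum_at(q_time[qi], iv_start[ii], iv_end[ii], iv_rate[ii])
  }
  out
}

# TRUE where at least one interval of the same stay covers the query time.
interval_any_match <- function(q_stay, q_time, iv_stay, iv_start, iv_end) {
  interval_rate_sum(q_stay, q_time, iv_stay, iv_start, iv_end,
                    rep(1, length(iv_stay))) > 0
}

#' Match corrected exposure windows to glucose measurements
#'
#' For each measurement, collects the effect windows of its stay that cover
#' the resolved time (`window_start <= t < window_end`) and derives the
#' sample-level exposure covariates: summed insulin rate (units/h), summed
#' dextrose rate (g/h), summed carbohydrate rate from nutrition (g/h), and
#' a glucocorticoid presence flag.
#'
#' @param glucose Curated glucose tibble with `resolved_time`.
#' @param windows Exposure tibble with corrected windows and effective
#'   rates; nutrition events must carry `carb_rate_g_h` ([carb_rate()]).
#' @return The glucose tibble with `insulin_rate_u_h`, `dextrose_rate_g_h`,
#'   `carb_rate_g_h`, `glucocorticoid` columns added.
#' @export
match_exposures <- function(glucose, windows) {
  need <- c("window_start", "window_end")
  if (!all(need %in% names(windows))) {
    abort("windows must be corrected with correct_window() first")
  }
  pick <- function(k) windows[windows$kind == k, , drop = FALSE]
  ins <- pick("insulin")
  dex <- pick("dextrose")
  gc_ <- pick("glucocorticoid")
  nut <- pick("enteral_nutrition")
  # windows whose rate cannot be quantified (unknown-content products)
  # contribute nothing to the sums; measurements covered ONLY by such
  # windows are removed during curation, not here
  if (nrow(nut) > 0 && "carb_rate_g_h" %in% names(nut)) {
    nut <- nut[!is.na(nut$carb_rate_g_h), , drop = FALSE]
  }
  glucose$insulin_rate_u_h <- interval_rate_sum(
    glucose$stay_id, glucose$resolved_time,
    ins$stay_id, ins$window_start, ins$window_end, ins$effective_rate
  )
  glucose$dextrose_rate_g_h <- interval_rate_sum(
    glucose$stay_id, glucose$resolved_time,
    dex$stay_id, dex$window_start, dex$window_end, dex$effective_rate
  )
  glucose$carb_rate_g_h <- interval_rate_sum(
    glucose$stay_id, glucose$resolved_time,
    nut$stay_id, nut$window_start, nut$window_end, nut$carb_rate_g_h
  )
  glucose$glucocorticoid <- interval_any_match(
    glucose$stay_id, glucose$resolved_time,
    gc_$stay_id, gc_$window_start, gc_$window_end
  )
  glucose
}

#' Derive per-measurement stay-context covariates
#'
#' Computes, for each curated measurement: days since ICU admission; time
#' to the next glucose sample in hours, computed against ALL measurements
#' of the stay (including those outside enteral-nutrition periods, so that
#' sampling frequency is not distorted by the nutrition restriction);
#' ventilation state and RASS score carried forward from the most recent
#' record at or before the measurement (`NA`/`none` before the first
#' record).
#'
#' @param glucose Curated glucose tibble with `resolved_time`.
#' @param stays Stays tibble.
#' @param all_glucose Full pre-restriction glucose tibble with
#'   `resolved_time` (deduplicated timeline of the same cohort).
#' @param ventilation Ventilation-events tibble (`stay_id`, `time`, `state`).
#' @param rass Rass-events tibble (`stay_id`, `time`, `rass`).
#' @return The glucose tibble with `days_since_admission`,
#'   `time_to_next_sample_h`, `ventilation`, `rass` columns added.
#' @export
derive_covariates <- function(glucose, stays, all_glucose, ventilation, rass) {
  adm <- stays$admit_time[match(glucose$stay_id, stays$stay_id)]
  glucose$days_since_admission <- diff_days(glucose$resolved_time, adm)

  next_after <- function(q, times) {
    # smallest time strictly greater than q, NA if none
    times <- sort(unique(as.numeric(times)))
    i <- findInterval(as.numeric(q), times) + 1L
    out <- rep(NA_real_, length(q))
    ok <- i <= length(times)
    out[ok] <- times[i[ok]]
    out
  }
  last_at_or_before <- function(q, times, values) {
    o <- order(as.numeric(times))
    i <- findInterval(as.numeric(q), as.numeric(times)[o])
    out <- rep(NA, length(q))
    ok <- i >= 1
    out[ok] <- values[o][i[ok]]
    out
  }
  tg <- split(seq_len(nrow(glucose)), glucose$stay_id)
  all_g <- split(as.numeric(all_glucose$resolved_time), all_glucose$stay_id)
  vent_g <- split(seq_len(nrow(ventilation)), ventilation$stay_id)
  rass_g <- split(seq_len(nrow(rass)), rass$stay_id)
  ttn <- rep(NA_real_, nrow(glucose))
  vent <- rep(NA_character_, nrow(glucose))
  rs <- rep(NA_integer_, nrow(glucose))
  for (sid in names(tg)) {
    qi <- tg[[sid]]
    q <- glucose$resolved_time[qi]
    if (!is.null(all_g[[sid]])) {
      nxt <- next_after(q, all_g[[sid]])
      ttn[qi] <- (nxt - as.numeric(q)) / 3600
    }
    vi <- vent_g[[sid]]
    if (!is.null(vi)) {
      vent[qi] <- last_at_or_before(q, ventilation$time[vi], ventilation$state[vi])
    }
    ri <- rass_g[[sid]]
    if (!is.null(ri)) {
      rs[qi] <- last_at_or_before(q, rass$time[ri], as.integer(rass$rass[ri]))
    }
  }
  glucose$time_to_next_sample_h <- ttn
  glucose$ventilation <- dplyr::coalesce(vent, "none")
  glucose$rass <- rs
  glucose
}

#' Build the analysis-row table from a validated bundle
#'
#' End-to-end construction of the modelling table: curation
#' ([curate_cohort()]), window correction and effective rates, carbohydrate
#' rate derivation, exposure matching, context covariates, and
#' categorisation of the continuous covariates.
#'
#' @param bundle A `glucirc_bundle`.
#' @return List with `rows` (analysis-row tibble in the fixed column order)
#'   and `report` (the curation report).
#' @export
build_analysis_table <- function(bundle) {
  cur <- curate_cohort(bundle)
  g <- cur$glucose
  med <- bundle$medication_events
  med$kind <- as.character(med$kind)
  nut <- bundle$nutrition_events
  nut$kind <- "enteral_nutrition"
  nut$subtype <- nut$product_id
  nut$amount <- NA_real_
  events <- dplyr::bind_rows(
    med[, c("stay_id", "kind", "subtype", "start_time", "end_time", "rate", "amount")],
    nut[, c("stay_id", "kind", "subtype", "start_time", "end_time", "rate", "amount")]
  )
  win <- effective_rate(correct_window(events))
  win$product_id <- ifelse(win$kind == "enteral_nutrition", win$subtype, NA_character_)
  win <- carb_rate(win, bundle$products)
  win$carb_rate_g_h[win$kind != "enteral_nutrition"] <- NA_real_

  g <- match_exposures(g, win)

  # sampling timeline: all in-stay measurements of included stays, deduped
  all_g <- resolve_glucose_times(bundle$glucose_events)
  all_g <- all_g[all_g$stay_id %in% cur$included_stays, , drop = FALSE]
  g <- derive_covariates(g, bundle$stays, all_g,
                         bundle$ventilation_events, bundle$rass_events)

  stays <- bundle$stays
  idx <- match(g$stay_id, stays$stay_id)
  rows <- tibble(
    stay_id = g$stay_id,
    patient_id = stays$patient_id[idx],
    glucose_mmol_l = g$value_mmol_l,
    hour_bin = g$hour_bin,
    age_cat = as.character(categorise_age(stays$age_years[idx])),
    sex = stays$sex[idx],
    diabetes = stays$diabetes[idx],
    carb_cat = as.character(categorise_carb(g$carb_rate_g_h)),
    insulin_cat = as.character(categorise_insulin(g$insulin_rate_u_h)),
    dextrose_cat = as.character(categorise_dextrose(g$dextrose_rate_g_h)),
    glucocorticoid = g$glucocorticoid,
    carb_rate_g_h = g$carb_rate_g_h,
    insulin_rate_u_h = g$insulin_rate_u_h,
    dextrose_rate_g_h = g$dextrose_rate_g_h,
    age_years = stays$age_years[idx],
    days_since_admission = g$days_since_admission,
    time_to_next_sample_h = g$time_to_next_sample_h,
    ventilation = g$ventilation,
    rass = g$rass,
    sample_type = g$sample_type
  )
  list(rows = rows, report = cur$report)
}
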