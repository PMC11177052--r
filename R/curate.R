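# Cohort selection and measurement-level cleaning.
#
# Pipeline order (documented and fixed): cohort selection at stay level,
# then per measurement: timestamp resolution -> validity filter ->
# simultaneous-measurement deduplication -> restriction to enteral
# nutrition. Each step reports rows in/out so the counts reconcile into an
# inclusion flowchart.

#' Resolve the measurement timestamp from chart and store time
#'
#' The chart time (the time of data entry) is the default proxy for when a
#' glucose sample was actually taken. When the store time (the time the
#' caregiver recorded the value) precedes the chart time, the store time is
#' the better proxy and is used instead. A missing store time falls back to
#' the chart time.
#'
#' @param chart_time POSIXct vector.
#' @param store_time POSIXct vector (may contain `NA`).
#' @return POSIXct vector of resolved timestamps.
#' @export
#' @examples
#' chart <- parse_timestamp("2120-03-01T10:00:00")
#' resolve_timestamp(chart, parse_timestamp("2120-03-01T09:45:00"))
resolve_timestamp <- function(chart_time, store_time) {
  if (any(is.na(chart_time))) {
    abort("chart_time must be present", class = "glucirc_domain_error")
  }
  use_store <- !is.na(store_time) & store_time < chart_time
  out <- chart_time
  out[use_store] <- store_time[use_store]
  out
}

#' Add resolved time and hour bin to glucose measurements
#'
#' @param glucose Glucose-events tibble.
#' @return Same tibble with `resolved_time` (POSIXct) and `hour_bin`
#'   (integer 0-23) columns.
#' @export
resolve_glucose_times <- function(glucose) {
  glucose |>
    dplyr::mutate(
      resolved_time = resolve_timestamp(chart_time, store_time),
      hour_bin = hour_of_day(resolved_time)
    )
}

#' Select ICU stays for the analysis cohort
#'
#' Keeps stays satisfying all four inclusion criteria: total length of stay
#' (admission to discharge) of at least 4 days; not a readmission; at least
#' one glucose measurement during the stay; at least one enteral-nutrition
#' event during the stay. "During the stay" means a resolved measurement
#' time (or nutrition interval overlap) within `[admit, discharge)`.
#'
#' @param stays Stays tibble.
#' @param glucose Glucose-events tibble (resolved times added if absent).
#' @param nutrition Nutrition-events tibble.
#' @return List with `included` (character vector of stay ids) and `report`
#'   (a [curation_report()] step table for the four criteria).
#' @export
select_cohort <- function(stays, glucose, nutrition) {
  if (!"resolved_time" %in% names(glucose)) {
    glucose <- resolve_glucose_times(glucose)
  }
  los_ok <- diff_days(stays$discharge_time, stays$admit_time) >= 4
  not_readmit <- !stays$is_readmission

  stay_key <- stays$stay_id
  adm <- stays$admit_time[match(glucose$stay_id, stay_key)]
  dis <- stays$discharge_time[match(glucose$stay_id, stay_key)]
  in_stay <- !is.na(adm) & glucose$resolved_time >= adm & glucose$resolved_time < dis
  has_glucose <- stay_key %in% unique(glucose$stay_id[in_stay])

  n_adm <- stays$admit_time[match(nutrition$stay_id, stay_key)]
  n_dis <- stays$discharge_time[match(nutrition$stay_id, stay_key)]
  nut_in_stay <- !is.na(n_adm) & nutrition$end_time > n_adm & nutrition$start_time < n_dis
  has_nutrition <- stay_key %in% unique(nutrition$stay_id[nut_in_stay])

  keep1 <- los_ok
  keep2 <- keep1 & not_readmit
  keep3 <- keep2 & has_glucose
  keep4 <- keep3 & has_nutrition
  steps <- tibble(
    step = c("los_ge_4_days", "not_readmission", "has_glucose", "has_enteral_nutrition"),
    rows_in = c(length(keep1), sum(keep1), sum(keep2), sum(keep3)),
    rows_out = c(sum(keep1), sum(keep2), sum(keep3), sum(keep4))
  )
  reasons <- dplyr::case_when(
    !los_ok ~ "los_lt_4_days",
    !not_readmit ~ "readmission",
    !has_glucose ~ "no_glucose_during_stay",
    !has_nutrition ~ "no_enteral_nutrition",
    TRUE ~ NA_character_
  )
  list(
    included = stay_key[keep4],
    report = steps,
    exclusions = tibble(stay_id = stay_key, reason = reasons) |>
      dplyr::filter(!is.na(reason))
  )
}

#' Apply sample-type validity limits to glucose values
#'
#' Drops measurements whose value exceeds the accuracy limit of their
#' measurement method: strictly above 27.8 mmol/L (500 mg/dL) for capillary
#' point-of-care tests, strictly above 55.6 mmol/L (1000 mg/dL) for
#' laboratory whole-blood and serum assays. Boundary values are kept.
#'
#' @param glucose Glucose-events tibble.
#' @return List with `kept` and `dropped` tibbles.
#' @export
apply_validity_filter <- function(glucose) {
  if (any(glucose$value_mmol_l <= 0, na.rm = TRUE)) {
    abort("non-positive glucose value", class = "glucirc_domain_error")
  }
  limit <- glucose_validity_limits[glucose$sample_type]
  over <- glucose$value_mmol_l > limit
  list(kept = glucose[!over, , drop = FALSE],
       dropped = glucose[over, , drop = FALSE])
}

#' Deduplicate simultaneous glucose measurements
#'
#' For measurements of the same stay at the same resolved time (second
#' resolution), keeps exactly one by sample-type preference: whole blood
#' over serum over capillary. A tie within the same sample type keeps the
#' first row in stable input order and emits a warning. Idempotent.
#'
#' @param glucose Glucose-events tibble with `resolved_time`.
#' @return Deduplicated tibble (original row order preserved).
#' @export
dedupe_simultaneous <- function(glucose) {
  if (!"resolved_time" %in% names(glucose)) {
    abort("resolved_time must be computed before deduplication")
  }
  pref <- match(glucose$sample_type, SAMPLE_TYPES) # 1 best .. 3 worst
  ord <- seq_len(nrow(glucose))
  key <- paste(glucose$stay_id, format_timestamp(glucose$resolved_time))
  # stable: order by key, then preference, then input order; keep group heads
  o <- order(key, pref, ord)
  first_of_group <- !duplicated(key[o])
  keep_idx <- sort(o[first_of_group])
  dup_groups <- split(pref[o], key[o])
  ties <- vapply(dup_groups, function(p) sum(p == p[1]) > 1, logical(1))
  if (any(ties)) {
    warn(sprintf(
      "%d group(s) of simultaneous measurements with the same sample type; kept first by input order",
      sum(ties)
    ))
  }
  glucose[keep_idx, , drop = FALSE]
}

#' Restrict glucose measurements to enteral-nutrition periods
#'
#' Keeps measurements whose resolved time falls inside at least one
#' enteral-nutrition interval, treated half-open `[start, end)`.
#' Measurements covered only by nutrition products whose carbohydrate
#' content is unknown are removed, because no carbohydrate administration
#' rate can be derived for them.
#'
#' @param glucose Glucose-events tibble with `resolved_time`.
#' @param nutrition Nutrition-events tibble.
#' @param products Product lookup tibble (`product_id`, `carb_g_ml`;
#'   `NA` content = unknown).
#' @return List with `kept`, `dropped_outside` (not during nutrition) and
#'   `dropped_unknown_product` tibbles.
#' @export
restrict_to_enteral_nutrition <- function(glucose, nutrition, products) {
  known <- products$product_id[!is.na(products$carb_g_ml)]
  covered <- interval_any_match(
    glucose$stay_id, glucose$resolved_time,
    nutrition$stay_id, nutrition$start_time, nutrition$end_time
  )
  nut_known <- nutrition[nutrition$product_id %in% known, , drop = FALSE]
  covered_known <- interval_any_match(
    glucose$stay_id, glucose$resolved_time,
    nut_known$stay_id, nut_known$start_time, nut_known$end_time
  )
  list(
    kept = glucose[covered_known, , drop = FALSE],
    dropped_outside = glucose[!covered, , drop = FALSE],
    dropped_unknown_product = glucose[covered & !covered_known, , drop = FALSE]
  )
}

#' Run the full measurement-level curation pipeline
#'
#' Applies, in order: cohort selection, timestamp resolution, validity
#' filtering, simultaneous-measurement deduplication, and restriction to
#' enteral-nutrition periods, and assembles the inclusion-flowchart counts.
#'
#' @param bundle A `glucirc_bundle`.
#' @return List with `glucose` (curated measurements with `resolved_time`
#'   and `hour_bin`), `included_stays`, and `report` (a `curation_report`).
#' @export
curate_cohort <- function(bundle) {
  sel <- select_cohort(bundle$stays, bundle$glucose_events, bundle$nutrition_events)
  g <- resolve_glucose_times(bundle$glucose_events)
  n0 <- nrow(g)
  g <- g[g$stay_id %in% sel$included, , drop = FALSE]
  adm <- bundle$stays$admit_time[match(g$stay_id, bundle$stays$stay_id)]
  dis <- bundle$stays$discharge_time[match(g$stay_id, bundle$stays$stay_id)]
  g <- g[g$resolved_time >= adm & g$resolved_time < dis, , drop = FALSE]
  n1 <- nrow(g)
  vf <- apply_validity_filter(g)
  n2 <- nrow(vf$kept)
  dd <- dedupe_simultaneous(vf$kept)
  n3 <- nrow(dd)
  en <- restrict_to_enteral_nutrition(
    dd, bundle$nutrition_events[bundle$nutrition_events$stay_id %in% sel$included, , drop = FALSE],
    bundle$products
  )
  n4 <- nrow(en$kept) + nrow(en$dropped_unknown_product)
  n5 <- nrow(en$kept)
  steps <- tibble(
    step = c("in_included_stay", "validity_filter", "dedupe_simultaneous",
             "during_enteral_nutrition", "known_carbohydrate_content"),
    rows_in = c(n0, n1, n2, n3, n4),
    rows_out = c(n1, n2, n3, n4, n5)
  )
  report <- structure(
    list(stay_steps = sel$report, stay_exclusions = sel$exclusions,
         measurement_steps = steps),
    class = "glucirc_curation_report"
  )
  list(glucose = en$kept, included_stays = sel$included, report = report)
}

#' @export
print.glucirc_curation_report <- function(x, ...) {
  cat("<curation report>\nStays:\n")
  print(as.data.frame(x$stay_steps), row.names = FALSE)
  cat("Glucose measurements:\n")
  print(as.data.frame(x$measurement_steps), row.names = FALSE)
  invisible(x)
}
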