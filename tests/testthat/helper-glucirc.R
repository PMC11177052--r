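# Shared fixtures and independent oracles for the test suite.

ts <- function(x) parse_timestamp(x)

# Small hand-built bundle: 2 stays, a handful of events.
toy_tables <- function() {
  list(
    stays = tibble::tibble(
      stay_id = c("s1", "s2"),
      patient_id = c("p1", "p2"),
      admit_time = ts(c("2120-03-01T00:00:00", "2120-03-05T12:00:00")),
      discharge_time = ts(c("2120-03-09T00:00:00", "2120-03-08T12:00:00")),
      is_readmission = c(FALSE, FALSE),
      age_years = c(62, 48),
      sex = c("male", "female"),
      diabetes = c(TRUE, FALSE),
      race = c("white", "unknown"),
      admission_type = c("emergency", "elective"),
      sofa_admission = c(8L, NA_integer_),
      oasis = c(40L, 35L),
      in_hospital_mortality = c(FALSE, TRUE)
    ),
    glucose_events = tibble::tibble(
      stay_id = c("s1", "s1", "s2"),
      chart_time = ts(c("2120-03-02T10:00:00", "2120-03-03T04:30:00",
                        "2120-03-06T08:00:00")),
      store_time = ts(c("2120-03-02T09:45:00", NA, "2120-03-06T08:30:00")),
      value_mmol_l = c(8.1, 6.4, 9.9),
      sample_type = c("whole_blood", "capillary", "serum")
    ),
    nutrition_events = tibble::tibble(
      stay_id = c("s1", "s2"),
      product_id = c("prodA", "prodB"),
      start_time = ts(c("2120-03-01T12:00:00", "2120-03-05T18:00:00")),
      end_time = ts(c("2120-03-05T12:00:00", "2120-03-08T00:00:00")),
      rate = c(50, 40)
    ),
    medication_events = tibble::tibble(
      stay_id = c("s1", "s1"),
      kind = c("insulin", "glucocorticoid"),
      subtype = c("short", NA_character_),
      start_time = ts(c("2120-03-02T08:00:00", "2120-03-02T06:00:00")),
      end_time = ts(c("2120-03-02T09:00:00", "2120-03-02T06:00:00")),
      rate = c(2, NA),
      amount = c(NA, NA)
    ),
    ventilation_events = tibble::tibble(
      stay_id = "s1", time = ts("2120-03-01T00:00:00"), state = "invasive"
    ),
    rass_events = tibble::tibble(
      stay_id = "s1", time = ts("2120-03-01T06:00:00"), rass = -3L
    ),
    products = tibble::tibble(
      product_id = c("prodA", "prodB", "prodU"),
      carb_g_ml = c(0.14, 0.12, NA)
    )
  )
}

toy_bundle <- function() validate_bundle(toy_tables())

# Generate a small cohort and its analysis rows, warnings silenced
# (simultaneous-measurement tie warnings are expected by construction).
quick_cohort <- function(n = 60, seed = 1, ...) {
  g <- generate_cohort(synth_config(n_patients = n, seed = seed, ...))
  bt <- suppressWarnings(build_analysis_table(g$tables))
  list(gen = g, rows = bt$rows, report = bt$report)
}

# Literal minute-scan oracle: marks, minute by minute, which corrected
# windows are active and sums their rates; exact for events and
# measurements on whole-minute boundaries.
minute_scan_oracle <- function(glucose, windows, value_col = "effective_rate") {
  out_ins <- numeric(nrow(glucose))
  out_dex <- numeric(nrow(glucose))
  out_carb <- numeric(nrow(glucose))
  out_gc <- logical(nrow(glucose))
  for (sid in unique(glucose$stay_id)) {
    qi <- which(glucose$stay_id == sid)
    wi <- windows[windows$stay_id == sid, , drop = FALSE]
    if (nrow(wi) == 0) next
    t0 <- min(as.numeric(wi$window_start), as.numeric(glucose$resolved_time[qi]))
    t1 <- max(as.numeric(wi$window_end), as.numeric(glucose$resolved_time[qi]))
    mins <- seq(floor(t0 / 60), ceiling(t1 / 60))
    acc <- list(insulin = numeric(length(mins)),
                dextrose = numeric(length(mins)),
                enteral_nutrition = numeric(length(mins)),
                glucocorticoid = numeric(length(mins)))
    for (k in seq_len(nrow(wi))) {
      s_min <- as.numeric(wi$window_start[k]) / 60
      e_min <- as.numeric(wi$window_end[k]) / 60
      active <- mins >= s_min & mins < e_min
      kind <- wi$kind[k]
      val <- if (kind == "glucocorticoid") 1
        else if (kind == "enteral_nutrition") wi$carb_rate_g_h[k]
        else wi[[value_col]][k]
      if (is.na(val)) next
      acc[[kind]][active] <- acc[[kind]][active] + val
    }
    pos <- match(floor(as.numeric(glucose$resolved_time[qi]) / 60), mins)
    out_ins[qi] <- acc$insulin[pos]
    out_dex[qi] <- acc$dextrose[pos]
    out_carb[qi] <- acc$enteral_nutrition[pos]
    out_gc[qi] <- acc$glucocorticoid[pos] > 0
  }
  tibble::tibble(insulin = out_ins, dextrose = out_dex, carb = out_carb,
                 glucocorticoid = out_gc)
}

# Build the corrected, quantified window table the way the pipeline does.
corrected_windows <- function(bundle) {
  med <- bundle$medication_events
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
  win
}

# First-harmonic (cosinor) peak estimate of a 24-point hourly profile;
# noise-robust compared to the raw argmax.
harmonic_peak_hour <- function(hour, value) {
  a <- stats::coef(stats::lm(value ~ cos(2 * pi * hour / 24) + sin(2 * pi * hour / 24)))
  phase <- atan2(a[3], a[2]) # radians of the cosine peak
  (round(phase * 24 / (2 * pi)) + 24) %% 24
}
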