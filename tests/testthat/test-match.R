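# Pharmacokinetic window corrections and exposure matching.

mk_event <- function(kind, subtype, start, end, rate = NA_real_,
                     amount = NA_real_, stay = "s1") {
  tibble::tibble(stay_id = stay, kind = kind, subtype = subtype,
                 start_time = ts(start), end_time = ts(end),
                 rate = rate, amount = amount)
}

test_that("window corrections reproduce the fixed pharmacokinetic offsets", {
  e <- dplyr::bind_rows(
    mk_event("insulin", "rapid", "2120-01-01T08:00:00", "2120-01-01T09:00:00", rate = 2),
    mk_event("insulin", "short", "2120-01-01T08:00:00", "2120-01-01T09:00:00", rate = 2),
    mk_event("insulin", "intermediate", "2120-01-01T08:00:00", "2120-01-01T09:00:00", rate = 2),
    mk_event("insulin", "long", "2120-01-01T08:00:00", "2120-01-01T09:00:00", rate = 2),
    mk_event("glucocorticoid", NA, "2120-01-01T10:00:00", "2120-01-01T10:30:00"),
    mk_event("dextrose", "push", "2120-01-01T10:15:00", "2120-01-01T10:15:00", amount = 5),
    mk_event("dextrose", "infusion", "2120-01-01T06:00:00", "2120-01-01T12:00:00", rate = 1),
    mk_event("enteral_nutrition", "prodA", "2120-01-01T00:00:00", "2120-01-02T00:00:00", rate = 50)
  )
  w <- correct_window(e)
  # insulin: start +0.5 h; end +2/4/10/12 h by action class
  expect_equal(w$window_start[1:4], rep(ts("2120-01-01T08:30:00"), 4))
  expect_equal(w$window_end[1:4],
               ts(c("2120-01-01T11:00:00", "2120-01-01T13:00:00",
                    "2120-01-01T19:00:00", "2120-01-01T21:00:00")))
  # glucocorticoid: end +24 h, start unchanged
  expect_equal(w$window_start[5], ts("2120-01-01T10:00:00"))
  expect_equal(w$window_end[5], ts("2120-01-02T10:30:00"))
  # dextrose push: 10 minutes from the push time
  expect_equal(w$window_end[6], ts("2120-01-01T10:25:00"))
  # dextrose infusion and nutrition: unchanged
  expect_equal(w$window_start[7:8], e$start_time[7:8])
  expect_equal(w$window_end[7:8], e$end_time[7:8])
  expect_error(correct_window(mk_event("insulin", NA, "2120-01-01T08:00:00",
                                       "2120-01-01T09:00:00", rate = 1)),
               class = "glucirc_domain_error")
})

test_that("window corrections are pure functions of the event fields", {
  e <- mk_event("insulin", "short", "2120-01-01T08:00:00", "2120-01-01T09:00:00",
                rate = 2)
  w1 <- correct_window(e)
  w2 <- correct_window(dplyr::bind_rows(e, e, e))
  expect_equal(w2$window_start, rep(w1$window_start, 3))
  expect_equal(w2$window_end, rep(w1$window_end, 3))
})

test_that("effective rates: infusions pass through, boluses spread over the window", {
  e <- dplyr::bind_rows(
    mk_event("dextrose", "push", "2120-01-01T10:15:00", "2120-01-01T10:15:00", amount = 5),
    mk_event("insulin", "short", "2120-01-01T08:00:00", "2120-01-01T10:00:00", rate = 2),
    mk_event("glucocorticoid", NA, "2120-01-01T10:00:00", "2120-01-01T10:00:00")
  )
  w <- effective_rate(correct_window(e))
  expect_equal(w$effective_rate[1], 30)    # 5 g over 10 min
  expect_equal(w$effective_rate[2], 2)     # unchanged
  expect_true(is.na(w$effective_rate[3]))  # presence only
})

test_that("carbohydrate rate is nutrition rate times product content", {
  products <- tibble::tibble(product_id = c("a", "b"),
                             carb_g_ml = c(0.14, 0.2))
  nut <- tibble::tibble(product_id = c("a", "a", "b", "zzz"),
                        rate = c(50, 0, 10, 50))
  out <- carb_rate(nut, products)
  expect_equal(out$carb_rate_g_h, c(7, 0, 2, NA))
  # random pairs equal independent recomputation
  withr::local_seed(11)
  nut2 <- tibble::tibble(product_id = sample(c("a", "b"), 200, TRUE),
                         rate = runif(200, 0, 100))
  out2 <- carb_rate(nut2, products)
  expect_equal(out2$carb_rate_g_h,
               nut2$rate * products$carb_g_ml[match(nut2$product_id,
                                                    products$product_id)])
})

test_that("concurrent same-kind windows sum; half-open bounds are respected", {
  e <- dplyr::bind_rows(
    mk_event("insulin", "short", "2120-01-01T06:00:00", "2120-01-01T10:00:00", rate = 1),
    mk_event("insulin", "short", "2120-01-01T08:00:00", "2120-01-01T09:00:00", rate = 2)
  )
  w <- effective_rate(correct_window(e))
  q <- function(x) {
    g <- resolve_glucose_times(tibble::tibble(
      stay_id = "s1", chart_time = ts(x), store_time = ts(NA_character_),
      value_mmol_l = 7, sample_type = "serum"))
    match_exposures(g, w)
  }
  # both corrected windows active at 09:00 (first: 06:30-14:00, second: 08:30-13:00)
  expect_equal(q("2120-01-01T09:00:00")$insulin_rate_u_h, 3)
  # outside every window
  out <- q("2120-01-02T12:00:00")
  expect_equal(out$insulin_rate_u_h, 0)
  expect_false(out$glucocorticoid)
  # exactly at a window start: matched; exactly at a window end: not
  expect_equal(q("2120-01-01T08:30:00")$insulin_rate_u_h, 3)
  expect_equal(q("2120-01-01T13:00:00")$insulin_rate_u_h, 1)
  expect_equal(q("2120-01-01T14:00:00")$insulin_rate_u_h, 0)
})

test_that("matched rates equal the minute-scan oracle on random synthetic stays", {
  g <- generate_cohort(synth_config(n_patients = 12, seed = 31))
  b <- g$tables
  glucose <- resolve_glucose_times(b$glucose_events)
  win <- corrected_windows(b)
  matched <- match_exposures(glucose, win)
  oracle <- minute_scan_oracle(glucose, win)
  expect_equal(matched$insulin_rate_u_h, oracle$insulin, tolerance = 1e-9)
  expect_equal(matched$dextrose_rate_g_h, oracle$dextrose, tolerance = 1e-9)
  expect_equal(dplyr::coalesce(matched$carb_rate_g_h, 0), oracle$carb,
               tolerance = 1e-9)
  expect_equal(matched$glucocorticoid, oracle$glucocorticoid)
})

test_that("extending windows never loses matched measurements", {
  g <- generate_cohort(synth_config(n_patients = 10, seed = 13))
  b <- g$tables
  glucose <- resolve_glucose_times(b$glucose_events)
  win <- corrected_windows(b)
  n_before <- sum(match_exposures(glucose, win)$insulin_rate_u_h > 0)
  win2 <- win
  ins <- win2$kind == "insulin"
  win2$window_end[ins] <- win2$window_end[ins] + 3600
  n_after <- sum(match_exposures(glucose, win2)$insulin_rate_u_h > 0)
  expect_gte(n_after, n_before)
})

test_that("stay-context covariates: elapsed days, next sample, carried-forward states", {
  stays <- toy_tables()$stays
  g <- resolve_glucose_times(tibble::tibble(
    stay_id = "s1",
    chart_time = ts(c("2120-03-03T12:00:00", "2120-03-03T13:30:00")),
    store_time = ts(rep(NA_character_, 2)),
    value_mmol_l = c(7, 8), sample_type = "serum"
  ))
  vent <- tibble::tibble(stay_id = "s1",
                         time = ts(c("2120-03-01T00:00:00", "2120-03-03T13:00:00")),
                         state = c("invasive", "none"))
  rass <- tibble::tibble(stay_id = "s1", time = ts("2120-03-02T00:00:00"),
                         rass = -2L)
  out <- derive_covariates(g, stays, g, vent, rass)
  expect_equal(out$days_since_admission, c(2.5, 2.5625))
  expect_equal(out$time_to_next_sample_h, c(1.5, NA))
  expect_equal(out$ventilation, c("invasive", "none"))
  expect_equal(out$rass, c(-2L, -2L))
})

test_that("time to next sample equals a brute-force nearest-later scan", {
  withr::local_seed(17)
  stays <- toy_tables()$stays
  times <- ts("2120-03-01T00:00:00") + sort(sample(0:(7 * 1440), 60)) * 60
  g <- resolve_glucose_times(tibble::tibble(
    stay_id = "s1", chart_time = times, store_time = ts(rep(NA_character_, 60)),
    value_mmol_l = 7, sample_type = "serum"
  ))
  sub <- g[sample(60, 25), ]
  out <- derive_covariates(sub, stays, g,
                           toy_tables()$ventilation_events,
                           toy_tables()$rass_events)
  brute <- vapply(seq_len(nrow(sub)), function(i) {
    later <- g$resolved_time[g$resolved_time > sub$resolved_time[i]]
    if (length(later) == 0) NA_real_
    else as.numeric(min(later) - sub$resolved_time[i], units = "hours")
  }, numeric(1))
  expect_equal(out$time_to_next_sample_h, brute)
})
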