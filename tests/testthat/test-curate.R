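# Cohort selection and measurement-level cleaning rules.

test_that("timestamp resolution prefers an earlier store time", {
  chart <- ts("2120-03-01T10:00:00")
  expect_equal(resolve_timestamp(chart, ts("2120-03-01T09:45:00")),
               ts("2120-03-01T09:45:00"))
  expect_equal(resolve_timestamp(chart, ts("2120-03-01T10:30:00")), chart)
  expect_equal(resolve_timestamp(chart, ts(NA_character_)), chart)
  expect_error(resolve_timestamp(ts(NA_character_), chart),
               class = "glucirc_domain_error")
})

test_that("hour bins floor to 0-23", {
  expect_equal(hour_of_day(ts("2120-03-01T00:00:00")), 0L)
  expect_equal(hour_of_day(ts("2120-03-01T10:59:59")), 10L)
  expect_equal(hour_of_day(ts("2120-03-01T23:59:59")), 23L)
})

test_that("validity limits keep boundary values and drop strictly-above values", {
  # exhaustive grid around the capillary limit
  vals <- seq(25.0, 30.0, by = 0.1)
  g <- tibble::tibble(stay_id = "s", chart_time = ts("2120-01-01T00:00:00"),
                      store_time = ts(NA_character_),
                      value_mmol_l = vals, sample_type = "capillary")
  vf <- apply_validity_filter(g)
  expect_equal(max(vf$kept$value_mmol_l), 27.8)
  expect_equal(min(vf$dropped$value_mmol_l), 27.9)
  # laboratory limit
  vals <- seq(54.0, 58.0, by = 0.1)
  for (st in c("serum", "whole_blood")) {
    g$sample_type <- st
    g2 <- g[seq_along(vals), ]; g2$value_mmol_l <- vals
    vf <- apply_validity_filter(g2)
    expect_equal(max(vf$kept$value_mmol_l), 55.6)
  }
  # serum 30 is fine; capillary 30 is not
  g3 <- g[1:2, ]
  g3$value_mmol_l <- c(30, 30)
  g3$sample_type <- c("serum", "capillary")
  vf <- apply_validity_filter(g3)
  expect_equal(vf$kept$sample_type, "serum")
  # non-positive values are a hard error
  g3$value_mmol_l <- c(0, 5)
  expect_error(apply_validity_filter(g3), class = "glucirc_domain_error")
})

test_that("simultaneous measurements dedupe by sample-type preference", {
  g <- tibble::tibble(
    stay_id = "s1",
    chart_time = ts(rep("2120-03-01T10:00:00", 2)),
    store_time = ts(c(NA, NA)),
    value_mmol_l = c(8.0, 7.5),
    sample_type = c("whole_blood", "capillary")
  )
  g <- resolve_glucose_times(g)
  out <- dedupe_simultaneous(g)
  expect_equal(out$value_mmol_l, 8.0)
  expect_equal(out$sample_type, "whole_blood")
  # a single measurement is unchanged; dedupe is idempotent
  single <- resolve_glucose_times(g[1, ])
  expect_equal(dedupe_simultaneous(single), single)
  expect_equal(dedupe_simultaneous(out), out)
})

test_that("dedupe matches a brute-force argmax-by-preference oracle on random groups", {
  withr::local_seed(42)
  n <- 400
  g <- tibble::tibble(
    stay_id = sample(c("a", "b", "c"), n, replace = TRUE),
    chart_time = ts("2120-03-01T00:00:00") + sample(0:30, n, replace = TRUE) * 3600,
    store_time = ts(rep(NA_character_, n)),
    value_mmol_l = round(runif(n, 4, 12), 1),
    sample_type = sample(c("whole_blood", "serum", "capillary"), n, replace = TRUE)
  )
  g <- resolve_glucose_times(g)
  out <- suppressWarnings(dedupe_simultaneous(g))
  pref <- c(whole_blood = 1, serum = 2, capillary = 3)
  oracle <- do.call(rbind, lapply(
    split(seq_len(n), paste(g$stay_id, g$resolved_time)),
    function(idx) {
      best <- idx[order(pref[g$sample_type[idx]], idx)][1]
      g[best, ]
    }
  ))
  oracle <- oracle[order(match(
    paste(oracle$stay_id, oracle$resolved_time, oracle$value_mmol_l),
    paste(out$stay_id, out$resolved_time, out$value_mmol_l))), ]
  expect_equal(nrow(out), nrow(oracle))
  expect_setequal(
    paste(out$stay_id, out$resolved_time, out$sample_type, out$value_mmol_l),
    paste(oracle$stay_id, oracle$resolved_time, oracle$sample_type,
          oracle$value_mmol_l)
  )
  # permutation invariance (no within-type ties in this check)
  g2 <- g[!duplicated(paste(g$stay_id, g$resolved_time, g$sample_type)), ]
  perm <- withr::with_seed(7, sample(nrow(g2)))
  a <- dedupe_simultaneous(g2)
  b <- dedupe_simultaneous(g2[perm, ])
  expect_setequal(paste(a$stay_id, a$resolved_time, a$value_mmol_l),
                  paste(b$stay_id, b$resolved_time, b$value_mmol_l))
})

test_that("cohort selection enforces all four inclusion criteria at the boundary", {
  tt <- toy_tables()
  # shrink stay s1 to LOS 3.9 days -> excluded
  tt$stays$discharge_time[1] <- tt$stays$admit_time[1] + 3.9 * 86400
  sel <- select_cohort(tt$stays, tt$glucose_events, tt$nutrition_events)
  expect_false("s1" %in% sel$included)
  expect_equal(sel$exclusions$reason[sel$exclusions$stay_id == "s1"],
               "los_lt_4_days")
  # restore to exactly 4.0 days -> included (stay s2 has LOS 3 days)
  tt$stays$discharge_time[1] <- tt$stays$admit_time[1] + 4 * 86400
  sel <- select_cohort(tt$stays, tt$glucose_events, tt$nutrition_events)
  expect_true("s1" %in% sel$included)
  expect_false("s2" %in% sel$included)
})

test_that("planted inclusion violations are recovered exactly by the cohort filter", {
  g <- generate_cohort(synth_config(n_patients = 80, seed = 21))
  b <- g$tables
  sel <- select_cohort(b$stays, b$glucose_events, b$nutrition_events)
  planted <- g$truth$planted_violations
  expect_setequal(sel$exclusions$stay_id, planted$stay_id)
  merged <- dplyr::inner_join(sel$exclusions, planted, by = "stay_id")
  expect_equal(merged$reason, merged$violation)
  # step counts reconcile: each step's output feeds the next step's input
  expect_equal(sel$report$rows_out[-nrow(sel$report)],
               sel$report$rows_in[-1])
})

test_that("nutrition restriction drops outside-interval and unknown-content measurements", {
  b <- toy_bundle()
  g <- resolve_glucose_times(tibble::tibble(
    stay_id = "s1",
    chart_time = ts(c("2120-03-01T11:59:00",  # 1 min before the run starts
                      "2120-03-02T00:00:00",  # inside, known product
                      "2120-03-06T00:00:00")), # inside an unknown-product run
    store_time = ts(rep(NA_character_, 3)),
    value_mmol_l = c(7, 7, 7),
    sample_type = rep("serum", 3)
  ))
  nut <- dplyr::bind_rows(
    b$nutrition_events,
    tibble::tibble(stay_id = "s1", product_id = "prodU",
                   start_time = ts("2120-03-05T12:00:00"),
                   end_time = ts("2120-03-07T00:00:00"), rate = 30)
  )
  res <- restrict_to_enteral_nutrition(g, nut, b$products)
  expect_equal(nrow(res$kept), 1)
  expect_equal(res$kept$chart_time, ts("2120-03-02T00:00:00"))
  expect_equal(nrow(res$dropped_outside), 1)
  expect_equal(nrow(res$dropped_unknown_product), 1)
})

test_that("measurement curation step counts reconcile into a flowchart", {
  qc <- quick_cohort(n = 60, seed = 5)
  ms <- qc$report$measurement_steps
  expect_true(all(ms$rows_out <= ms$rows_in))
  expect_equal(ms$rows_out[-nrow(ms)], ms$rows_in[-1])
})

test_that("categorisation bands follow the documented inclusive upper bounds", {
  expect_equal(as.character(categorise_insulin(c(0, 1.5, 1.51, 3, 3.01))),
               c("0", "0<x<=1.5", "1.5<x<=3", "1.5<x<=3", ">3"))
  expect_equal(as.character(categorise_carb(c(4.5, 6.5, 8.5, 8.6))),
               c("<=4.5", "4.5<x<=6.5", "6.5<x<=8.5", ">8.5"))
  expect_equal(as.character(categorise_dextrose(c(0, 0.5, 2, 2.5))),
               c("0", "0<x<=0.5", "0.5<x<=2", ">2"))
  expect_equal(as.character(categorise_age(c(54.9, 55, 65, 65.5, 75, 76))),
               c("<55", "55-65", "55-65", "66-75", "66-75", ">75"))
  expect_error(categorise_insulin(-0.1), class = "glucirc_domain_error")
  expect_error(categorise_age(-1), class = "glucirc_domain_error")
})

test_that("categorisation agrees with a brute-force boundary oracle on random rates", {
  withr::local_seed(9)
  x <- c(runif(10000, 0, 12), 0, 1.5, 3, 4.5, 6.5, 8.5, 0.5, 2)
  band4 <- function(x, e1, e2, e3, labs) {
    vapply(x, function(v) {
      if (v <= e1) labs[1] else if (v <= e2) labs[2]
      else if (v <= e3) labs[3] else labs[4]
    }, character(1))
  }
  expect_equal(as.character(categorise_carb(x)),
               band4(x, 4.5, 6.5, 8.5, levels(categorise_carb(0))))
  expect_equal(as.character(categorise_insulin(x)),
               band4(x, 0, 1.5, 3, levels(categorise_insulin(0))))
  expect_equal(as.character(categorise_dextrose(x)),
               band4(x, 0, 0.5, 2, levels(categorise_dextrose(0))))
})
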