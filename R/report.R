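# Descriptive outputs and the end-to-end pipeline driver.

#' Plot an hourly EMM profile
#'
#' Optional convenience plot of a [emm_profile()] (point estimates with
#' their confidence ribbon over the 24-h day). Requires ggplot2; all
#' plotted numbers are exactly the profile's columns, which
#' [run_pipeline()] also writes as CSV.
#'
#' @param profile A `glucirc_emm_profile` (or any tibble with `hour`,
#'   `emm`, `ci_low`, `ci_high`).
#' @return A ggplot object.
#' @export
plot_emm_profile <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_emm_profile() needs the ggplot2 package")
  }
  ggplot2::ggplot(tibble::as_tibble(profile),
                  ggplot2::aes(x = hour, y = emm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_low, ymax = ci_high),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = seq(0, 23, 3)) +
    ggplot2::labs(x = "hour of day", y = "adjusted glucose (mmol/L)") +
    ggplot2::theme_minimal()
}

#' Per-patient normalised glucose values
#'
#' Removes between-patient baseline differences before plotting crude time
#' courses: centring subtracts each patient's mean; z-scoring additionally
#' divides by the patient's standard deviation (single-measurement patients
#' get 0 under both methods).
#'
#' @param rows Analysis-row tibble.
#' @param method `"centre"` (default) or `"zscore"`.
#' @return The tibble with a `glucose_normalised` column.
#' @export
normalise_per_patient <- function(rows, method = c("centre", "zscore")) {
  method <- match.arg(method)
  rows |>
    dplyr::group_by(patient_id) |>
    dplyr::mutate(glucose_normalised = {
      centred <- glucose_mmol_l - mean(glucose_mmol_l)
      if (method == "zscore") {
        s <- sd(glucose_mmol_l)
        if (is.na(s) || s == 0) centred * 0 else centred / s
      } else {
        centred
      }
    }) |>
    dplyr::ungroup()
}

#' Crude hourly mean of (optionally normalised) glucose
#'
#' @param rows Analysis-row tibble (with `glucose_normalised` if
#'   `normalised = TRUE`).
#' @param normalised Use the per-patient normalised values.
#' @return Tibble: `hour`, `mean_glucose`, `n`.
#' @export
crude_hourly_means <- function(rows, normalised = FALSE) {
  v <- if (normalised) rows$glucose_normalised else rows$glucose_mmol_l
  tibble(hour = rows$hour_bin, value = v) |>
    dplyr::group_by(hour) |>
    dplyr::summarise(mean_glucose = mean(value), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(hour)
}

#' Hourly distribution tables for the report
#'
#' 24-row tables of the number of included glucose measurements and the
#' mean enteral-nutrition dosing rate (at the measurement times) by hour of
#' day. Counts sum to the number of rows.
#'
#' @param rows Analysis-row tibble.
#' @return List of tibbles: `counts` (`hour`, `n_measurements`),
#'   `nutrition_rate` (`hour`, `mean_rate` in g carbohydrate/h, `n`).
#' @export
distribution_tables <- function(rows) {
  all_hours <- tibble(hour = 0:23)
  counts <- rows |>
    dplyr::count(hour = hour_bin, name = "n_measurements") |>
    dplyr::right_join(all_hours, by = "hour") |>
    dplyr::mutate(n_measurements = dplyr::coalesce(n_measurements, 0L)) |>
    dplyr::arrange(hour)
  rate <- rows |>
    dplyr::group_by(hour = hour_bin) |>
    dplyr::summarise(mean_rate = mean(carb_rate_g_h), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::right_join(all_hours, by = "hour") |>
    dplyr::arrange(hour)
  list(counts = counts, nutrition_rate = rate)
}

#' Run the full analysis pipeline and write its artifact directory
#'
#' Executes curation, exposure matching, the model sequence with
#' likelihood-ratio tests, the hourly profile, the gradient-boosted-tree
#' cross-check, the subgroup analyses, and the descriptive tables, writing
#' every result as CSV/JSON into `out_dir` together with a reproducibility
#' manifest (input hashes, seed, package version). Figures, if ever drawn,
#' are rendered from these CSVs — the files contain exactly the plotted
#' numbers.
#'
#' @param input Either a `glucirc_bundle`, a result of [generate_cohort()],
#'   or a named list of CSV paths for [read_tables()].
#' @param out_dir Artifact directory (created if needed).
#' @param seed Seed for the attribution-sample draw.
#' @param run_subgroups,run_gbm Toggles for the heavier stages.
#' @return Invisibly, a list with the in-memory results (`rows`, `report`,
#'   `models`, `lrt`, `emm`, `shap`, `subgroups`, `manifest`).
#' @export
run_pipeline <- function(input, out_dir, seed = 1L,
                         run_subgroups = TRUE, run_gbm = TRUE) {
  bundle <- if (inherits(input, "glucirc_bundle")) {
    input
  } else if (is.list(input) && !is.null(input$tables) &&
             inherits(input$tables, "glucirc_bundle")) {
    input$tables
  } else {
    read_tables(input)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  bt <- build_analysis_table(bundle)
  rows <- bt$rows
  write_analysis_table(rows, file.path(out_dir, "analysis_rows.csv"))
  jsonlite::write_json(
    list(stays = bt$report$stay_steps, measurements = bt$report$measurement_steps),
    file.path(out_dir, "curation_report.json")
  )

  ms <- fit_model_sequence(rows)
  lrts <- list(
    m1_vs_m2 = lrt(ms$fits$ML$m1, ms$fits$ML$m2),
    m2_vs_m3 = lrt(ms$fits$ML$m2, ms$fits$ML$m3),
    m3_vs_m4 = lrt(ms$fits$ML$m3, ms$fits$ML$m4)
  )
  fit_json <- lapply(ms$summaries, function(s) {
    list(model_id = s$model_id, objective = s$fit_objective,
         n_fixed_params = s$n_fixed_params,
         log_likelihood = s$log_likelihood,
         random_intercept_variance = s$random_intercept_variance,
         residual_variance = s$residual_variance,
         coefficients = s$coefficients)
  })
  jsonlite::write_json(fit_json, file.path(out_dir, "model_fits.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(lrts, function(l) list(chi_square = l$chi_square, df = l$df,
                                  p_value = l$p_value)),
    file.path(out_dir, "lrt.json"), auto_unbox = TRUE, digits = NA
  )

  prof <- emm_profile(ms$fits$ML$m4)
  readr::write_csv(tibble::as_tibble(prof), file.path(out_dir, "emm_profile.csv"))

  norm <- normalise_per_patient(rows)
  readr::write_csv(crude_hourly_means(norm, normalised = TRUE),
                   file.path(out_dir, "crude_hourly_means.csv"))
  dist <- distribution_tables(rows)
  readr::write_csv(dist$counts, file.path(out_dir, "hourly_counts.csv"))
  readr::write_csv(dist$nutrition_rate, file.path(out_dir, "hourly_nutrition_rate.csv"))

  shap <- NULL
  if (run_gbm) {
    shap <- fit_gbm_shap(rows, seed = seed)
    readr::write_csv(shap$hourly, file.path(out_dir, "shap_profile.csv"))
    readr::write_csv(shap$ranking, file.path(out_dir, "shap_ranking.csv"))
  }

  sg <- NULL
  if (run_subgroups) {
    specs <- subgroup_specs(bundle$stays, bundle$medication_events)
    sg <- run_subgroup_analysis(rows, specs)
    readr::write_csv(sg$counts, file.path(out_dir, "subgroup_counts.csv"))
    readr::write_csv(sg$profiles, file.path(out_dir, "subgroup_profiles.csv"))
    if (nrow(sg$skipped) > 0) {
      readr::write_csv(sg$skipped, file.path(out_dir, "subgroup_skipped.csv"))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("glucirc")),
    seed = seed,
    n_rows = nrow(rows),
    n_patients = length(unique(rows$patient_id)),
    table_hashes = vapply(
      names(glucirc_schemas()),
      function(nm) {
        df <- bundle[[nm]]
        for (cn in names(df)) {
          if (inherits(df[[cn]], "POSIXct")) df[[cn]] <- format_timestamp(df[[cn]])
        }
        rlang::hash(df)
      },
      character(1)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)

  invisible(list(rows = rows, report = bt$report, models = ms, lrt = lrts,
                 emm = prof, shap = shap, subgroups = sg, manifest = manifest))
}
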