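# Table schemas and validated CSV I/O.
#
# The pipeline consumes flat CSV event tables (one bundle per cohort):
#   stays, glucose_events, nutrition_events, medication_events,
#   ventilation_events, rass_events, products.
# CSV dialect: comma-separated, UTF-8, header row, RFC-4180 quoting,
# ISO-8601 timestamps (YYYY-MM-DDTHH:MM:SS), literal "NA" as the missing
# sentinel in every column.

SAMPLE_TYPES <- c("whole_blood", "serum", "capillary")
EXPOSURE_KINDS <- c("enteral_nutrition", "insulin", "dextrose", "glucocorticoid")
INSULIN_CLASSES <- c("rapid", "short", "intermediate", "long")
DEXTROSE_MODES <- c("infusion", "push")
VENT_STATES <- c("invasive", "non_invasive", "none")

# Column order of the analysis-row table, fixed and documented.
ANALYSIS_COLS <- c(
  "stay_id", "patient_id", "glucose_mmol_l", "hour_bin",
  "age_cat", "sex", "diabetes",
  "carb_cat", "insulin_cat", "dextrose_cat", "glucocorticoid",
  "carb_rate_g_h", "insulin_rate_u_h", "dextrose_rate_g_h",
  "age_years", "days_since_admission", "time_to_next_sample_h",
  "ventilation", "rass", "sample_type"
)

glucirc_schemas <- function() {
  col <- function(type, allow_na = FALSE, levels = NULL, min = NULL) {
    list(type = type, allow_na = allow_na, levels = levels, min = min)
  }
  list(
    stays = list(
      stay_id = col("id"),
      patient_id = col("id"),
      admit_time = col("timestamp"),
      discharge_time = col("timestamp"),
      is_readmission = col("logical"),
      age_years = col("number", min = 0),
      sex = col("enum", levels = c("male", "female")),
      diabetes = col("logical"),
      race = col("id"),
      admission_type = col("enum", levels = c("elective", "emergency")),
      sofa_admission = col("integer", allow_na = TRUE, min = 0),
      oasis = col("integer", allow_na = TRUE, min = 0),
      in_hospital_mortality = col("logical")
    ),
    glucose_events = list(
      stay_id = col("id"),
      chart_time = col("timestamp"),
      store_time = col("timestamp", allow_na = TRUE),
      value_mmol_l = col("number"),
      sample_type = col("enum", levels = SAMPLE_TYPES)
    ),
    nutrition_events = list(
      stay_id = col("id"),
      product_id = col("id"),
      start_time = col("timestamp"),
      end_time = col("timestamp"),
      rate = col("number", min = 0)
    ),
    medication_events = list(
      stay_id = col("id"),
      kind = col("enum", levels = c("insulin", "dextrose", "glucocorticoid")),
      subtype = col("id", allow_na = TRUE),
      start_time = col("timestamp"),
      end_time = col("timestamp"),
      rate = col("number", allow_na = TRUE, min = 0),
      amount = col("number", allow_na = TRUE, min = 0)
    ),
    ventilation_events = list(
      stay_id = col("id"),
      time = col("timestamp"),
      state = col("enum", levels = VENT_STATES)
    ),
    rass_events = list(
      stay_id = col("id"),
      time = col("timestamp"),
      rass = col("integer", min = -5)
    ),
    products = list(
      product_id = col("id"),
      carb_g_ml = col("number", allow_na = TRUE, min = 0)
    )
  )
}

coerce_column <- function(x, spec) {
  # returns list(values, bad = logical rows that failed coercion)
  n <- length(x)
  if (spec$type == "timestamp" && inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    bad <- if (spec$allow_na) rep(FALSE, n) else is.na(x)
    return(list(values = x, bad = bad))
  }
  x_chr <- as.character(x)
  x_chr[!is.na(x_chr) & x_chr == ""] <- NA_character_
  miss <- is.na(x_chr)
  bad <- rep(FALSE, n)
  vals <- switch(spec$type,
    id = x_chr,
    timestamp = {
      out <- as.POSIXct(x_chr, format = TS_FORMAT, tz = "UTC")
      bad <- !miss & is.na(out)
      out
    },
    number = {
      out <- suppressWarnings(as.numeric(x_chr))
      bad <- !miss & is.na(out)
      if (!is.null(spec$min)) bad <- bad | (!is.na(out) & out < spec$min)
      out
    },
    integer = {
      num <- suppressWarnings(as.numeric(x_chr))
      bad <- !miss & (is.na(num) | num != round(num))
      if (!is.null(spec$min)) bad <- bad | (!is.na(num) & num < spec$min)
      as.integer(round(num))
    },
    logical = {
      out <- rep(NA, n)
      out[!miss & tolower(x_chr) %in% c("true", "t", "1")] <- TRUE
      out[!miss & tolower(x_chr) %in% c("false", "f", "0")] <- FALSE
      bad <- !miss & is.na(out)
      out
    },
    enum = {
      bad <- !miss & !(x_chr %in% spec$levels)
      x_chr
    },
    abort(paste("unknown column type", spec$type))
  )
  if (!spec$allow_na) bad <- bad | miss
  list(values = vals, bad = bad)
}

#' Validate and coerce one raw table against its schema
#'
#' @param raw Data frame with character (or already-typed) columns.
#' @param name Table name (one of the bundle table names).
#' @return List with `data` (validated tibble), `errors` (tibble of rejected
#'   rows: `table`, `row`, `message`).
#' @keywords internal
validate_table <- function(raw, name) {
  schema <- glucirc_schemas()[[name]]
  if (is.null(schema)) abort(paste("unknown table:", name))
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols) > 0) {
    abort(
      sprintf(
        "table '%s': missing required column(s): %s", name,
        paste(missing_cols, collapse = ", ")
      ),
      class = "glucirc_schema_error"
    )
  }
  raw <- raw[names(schema)]
  n <- nrow(raw)
  msgs <- vector("list", length(schema))
  out <- vector("list", length(schema))
  for (i in seq_along(schema)) {
    cn <- names(schema)[i]
    cc <- coerce_column(raw[[cn]], schema[[cn]])
    out[[i]] <- cc$values
    msgs[[i]] <- ifelse(cc$bad, cn, NA_character_)
  }
  names(out) <- names(schema)
  df <- tibble::as_tibble(out)
  bad_cols <- do.call(cbind, msgs)
  bad_row <- rowSums(!is.na(bad_cols)) > 0
  # table-level invariants on rows that passed column coercion
  inv_msg <- rep(NA_character_, n)
  chk <- function(rows, message) {
    rows[is.na(rows)] <- FALSE
    inv_msg[!bad_row & rows & is.na(inv_msg)] <<- message
  }
  if (name == "stays") {
    chk(df$discharge_time <= df$admit_time, "discharge_time not after admit_time")
  }
  if (name == "glucose_events") {
    chk(df$value_mmol_l <= 0, "non-positive glucose value")
  }
  if (name == "nutrition_events") {
    chk(df$end_time < df$start_time, "end_time before start_time")
  }
  if (name == "medication_events") {
    chk(df$end_time < df$start_time, "end_time before start_time")
    is_ins_dex <- df$kind %in% c("insulin", "dextrose")
    chk(is_ins_dex & is.na(df$rate) & is.na(df$amount),
        "insulin/dextrose event needs exactly one of rate or amount")
    chk(is_ins_dex & !is.na(df$rate) & !is.na(df$amount),
        "insulin/dextrose event needs exactly one of rate or amount")
    chk(df$kind == "insulin" & !(df$subtype %in% INSULIN_CLASSES),
        "insulin event without a valid action class")
    chk(df$kind == "dextrose" & !(df$subtype %in% DEXTROSE_MODES),
        "dextrose event without a valid mode")
  }
  if (name == "rass_events") {
    chk(df$rass > 4L, "RASS outside -5..4")
  }
  reject <- bad_row | !is.na(inv_msg)
  messages <- character(0)
  rows <- integer(0)
  if (any(reject)) {
    rows <- which(reject)
    messages <- vapply(rows, function(r) {
      if (bad_row[r]) {
        cols <- bad_cols[r, ]
        paste0("invalid or missing value in column(s): ",
               paste(cols[!is.na(cols)], collapse = ", "))
      } else {
        inv_msg[r]
      }
    }, character(1))
  }
  list(
    data = df[!reject, , drop = FALSE],
    errors = tibble(table = rep(name, length(rows)), row = rows,
                    message = messages)
  )
}

#' Read and validate a bundle of cohort CSV tables
#'
#' Reads the flat event tables that make up one cohort and validates every
#' row against the documented schemas. Rows violating an invariant are
#' rejected (never silently altered) and reported in the `row_errors`
#' element; a missing required column is a hard schema error.
#'
#' @param paths Named list/vector of file paths. Recognised names:
#'   `stays`, `glucose_events`, `nutrition_events`, `medication_events`,
#'   `ventilation_events`, `rass_events`, `products`. `stays` and
#'   `glucose_events` are required; the remaining tables default to empty.
#' @return A `glucirc_bundle`: named list of validated tibbles plus a
#'   `row_errors` tibble (`table`, `row`, `message`; `row` is the data row
#'   number, header excluded).
#' @export
read_tables <- function(paths) {
  paths <- as.list(paths)
  unknown <- setdiff(names(paths), names(glucirc_schemas()))
  if (length(unknown) > 0) {
    abort(paste("unknown table name(s):", paste(unknown, collapse = ", ")))
  }
  for (req in c("stays", "glucose_events")) {
    if (is.null(paths[[req]])) abort(paste("missing required table:", req))
  }
  raws <- lapply(paths, function(p) {
    if (!file.exists(p)) {
      abort(paste("file not found:", p), class = "glucirc_io_error")
    }
    readr::read_csv(p, col_types = readr::cols(.default = readr::col_character()),
                    na = "NA", progress = FALSE)
  })
  validate_bundle(raws)
}

#' Validate an in-memory list of raw tables into a bundle
#'
#' Same contract as [read_tables()] but starting from data frames, which is
#' how the synthetic generator hands its tables over.
#'
#' @param tables Named list of data frames.
#' @return A `glucirc_bundle`.
#' @export
validate_bundle <- function(tables) {
  schemas <- glucirc_schemas()
  bundle <- list()
  errors <- list()
  for (name in names(schemas)) {
    if (is.null(tables[[name]])) {
      empty <- lapply(schemas[[name]], function(spec) {
        switch(spec$type,
          timestamp = as.POSIXct(character(0), tz = "UTC"),
          number = numeric(0), integer = integer(0),
          logical = logical(0), character(0))
      })
      bundle[[name]] <- tibble::as_tibble(empty)
      next
    }
    v <- validate_table(tables[[name]], name)
    bundle[[name]] <- v$data
    errors[[name]] <- v$errors
  }
  bundle$row_errors <- dplyr::bind_rows(errors)
  structure(bundle, class = c("glucirc_bundle", "list"))
}

#' @export
print.glucirc_bundle <- function(x, ...) {
  cat("<glucirc_bundle>\n")
  for (name in names(glucirc_schemas())) {
    cat(sprintf("  %-20s %6d rows\n", name, nrow(x[[name]])))
  }
  if (nrow(x$row_errors) > 0) {
    cat(sprintf("  %d row(s) rejected during validation\n", nrow(x$row_errors)))
  }
  invisible(x)
}

#' Write a cohort bundle to a directory of CSV files
#'
#' @param bundle A `glucirc_bundle`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_tables <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  schemas <- glucirc_schemas()
  paths <- character(0)
  for (name in names(schemas)) {
    df <- bundle[[name]]
    for (cn in names(df)) {
      if (inherits(df[[cn]], "POSIXct")) df[[cn]] <- format_timestamp(df[[cn]])
    }
    p <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(df, p, na = "NA", progress = FALSE)
    paths[name] <- p
  }
  invisible(paths)
}

#' Write the analysis-row table to CSV
#'
#' Writes one row per curated, exposure-matched glucose measurement in the
#' fixed, documented column order. Missing values (`rass`,
#' `time_to_next_sample_h`) are written as the literal sentinel `NA`, never
#' as an empty string. The file round-trips losslessly through
#' [read_analysis_table()].
#'
#' @param rows Analysis-row tibble (as produced by [build_analysis_table()]).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_analysis_table <- function(rows, path) {
  missing_cols <- setdiff(ANALYSIS_COLS, names(rows))
  if (length(missing_cols) > 0) {
    abort(paste("analysis table missing column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  out <- rows[ANALYSIS_COLS]
  ok <- tryCatch({
    readr::write_csv(out, path, na = "NA", progress = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(paste("cannot write analysis table:", conditionMessage(ok)),
          class = "glucirc_io_error")
  }
  invisible(path)
}

#' Read an analysis-row table written by [write_analysis_table()]
#'
#' @param path CSV path.
#' @return Tibble in the fixed column order.
#' @export
read_analysis_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste("file not found:", path), class = "glucirc_io_error")
  }
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      stay_id = readr::col_character(),
      patient_id = readr::col_character(),
      glucose_mmol_l = readr::col_double(),
      hour_bin = readr::col_integer(),
      age_cat = readr::col_character(),
      sex = readr::col_character(),
      diabetes = readr::col_logical(),
      carb_cat = readr::col_character(),
      insulin_cat = readr::col_character(),
      dextrose_cat = readr::col_character(),
      glucocorticoid = readr::col_logical(),
      carb_rate_g_h = readr::col_double(),
      insulin_rate_u_h = readr::col_double(),
      dextrose_rate_g_h = readr::col_double(),
      age_years = readr::col_double(),
      days_since_admission = readr::col_double(),
      time_to_next_sample_h = readr::col_double(),
      ventilation = readr::col_character(),
      rass = readr::col_integer(),
      sample_type = readr::col_character()
    ),
    na = "NA", progress = FALSE
  )
  df[ANALYSIS_COLS]
}
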