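# Categorisation of continuous covariates for the mixed-effects models.
#
# Band edges follow the model's reference-table labels; every non-reference
# band has an INCLUSIVE upper bound. Zero is its own (reference) level for
# insulin and dextrose because "none administered" is qualitatively distinct
# from a small dose.

AGE_LEVELS <- c("<55", "55-65", "66-75", ">75")
CARB_LEVELS <- c("<=4.5", "4.5<x<=6.5", "6.5<x<=8.5", ">8.5")
INSULIN_LEVELS <- c("0", "0<x<=1.5", "1.5<x<=3", ">3")
DEXTROSE_LEVELS <- c("0", "0<x<=0.5", "0.5<x<=2", ">2")

#' Categorise age in years
#'
#' Bands `<55`, `55-65`, `66-75`, `>75`. Integer band edges; ages in
#' `[55, 65]` fall in the second band and `(65, 75]` in the third, closing
#' the 65/66 gap of the printed labels.
#'
#' @param age_years Non-negative numeric vector.
#' @return Factor with levels `r paste(AGE_LEVELS, collapse = ", ")`.
#' @export
categorise_age <- function(age_years) {
  stopifnot(is.numeric(age_years))
  if (any(!is.na(age_years) & age_years < 0)) {
    abort("negative age", class = "glucirc_domain_error")
  }
  labs <- ifelse(age_years < 55, AGE_LEVELS[1],
          ifelse(age_years <= 65, AGE_LEVELS[2],
          ifelse(age_years <= 75, AGE_LEVELS[3], AGE_LEVELS[4])))
  factor(labs, levels = AGE_LEVELS)
}

rate_bands <- function(x, edges, levels, what) {
  stopifnot(is.numeric(x))
  if (any(!is.na(x) & x < 0)) {
    abort(paste("negative", what, "rate"), class = "glucirc_domain_error")
  }
  labs <- ifelse(x <= edges[1], levels[1],
          ifelse(x <= edges[2], levels[2],
          ifelse(x <= edges[3], levels[3], levels[4])))
  factor(labs, levels = levels)
}

#' Categorise carbohydrate administration rate (g/h)
#'
#' Bands `<=4.5` (reference), `(4.5, 6.5]`, `(6.5, 8.5]`, `>8.5` g/h.
#'
#' @param rate_g_h Non-negative numeric vector.
#' @return Factor with the four carbohydrate bands.
#' @export
categorise_carb <- function(rate_g_h) {
  rate_bands(rate_g_h, c(4.5, 6.5, 8.5), CARB_LEVELS, "carbohydrate")
}

#' Categorise insulin administration rate (units/h)
#'
#' Bands `0` (reference, exactly zero), `(0, 1.5]`, `(1.5, 3]`, `>3`.
#'
#' @param rate_u_h Non-negative numeric vector.
#' @return Factor with the four insulin bands.
#' @export
categorise_insulin <- function(rate_u_h) {
  rate_bands(rate_u_h, c(0, 1.5, 3), INSULIN_LEVELS, "insulin")
}

#' Categorise dextrose administration rate (g/h)
#'
#' Bands `0` (reference, exactly zero), `(0, 0.5]`, `(0.5, 2]`, `>2`.
#'
#' @param rate_g_h Non-negative numeric vector.
#' @return Factor with the four dextrose bands.
#' @export
categorise_dextrose <- function(rate_g_h) {
  rate_bands(rate_g_h, c(0, 0.5, 2), DEXTROSE_LEVELS, "dextrose")
}
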