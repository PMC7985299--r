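#' Generate an age-specific incidence / mortality rate table
#'
#' Builds a synthetic stand-in for population rate tables: one row per 1-year
#' age band with a breast-cancer incidence rate and an all-cause mortality
#' rate, both per person-year.
#'
#' @param base_incidence Incidence rate (per person-year, >= 0) at the first
#'   age band.
#' @param base_mortality Mortality rate (per person-year, >= 0) at the first
#'   age band.
#' @param age_range Length-2 integer vector, inclusive first and last age.
#' @param incidence_shape `list(family = "constant")` or
#'   `list(family = "loglinear", slope = s)` with rate
#'   `base * exp(s * (age - age_range[1]))`.
#' @param mortality_shape `list(family = "constant")` or
#'   `list(family = "gompertz", rate = g)` with rate
#'   `base * exp(g * (age - age_range[1]))` (strictly increasing for g > 0).
#' @return Tibble with `age`, `incidence_rate`, `mortality_rate`.
#' @export
generate_rate_table <- function(base_incidence, base_mortality,
                                age_range = c(50, 90),
                                incidence_shape = list(family = "constant"),
                                mortality_shape = list(family = "constant")) {
  if (base_incidence < 0 || base_mortality < 0)
    stop("rates must be >= 0", call. = FALSE)
  stopifnot(length(age_range) == 2, age_range[2] >= age_range[1])
  age <- seq.int(age_range[1], age_range[2])
  shape_col <- function(base, shape) {
    switch(shape$family,
           constant = rep(base, length(age)),
           loglinear = base * exp(shape$slope * (age - age[1])),
           gompertz = base * exp(shape$rate * (age - age[1])),
           stop("unknown shape family: ", shape$family, call. = FALSE))
  }
  tibble::tibble(age = age,
                 incidence_rate = shape_col(base_incidence, incidence_shape),
                 mortality_rate = shape_col(base_mortality, mortality_shape))
}
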