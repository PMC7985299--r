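#' Specify a synthetic nested case-control cohort
#'
#' Parameters for [generate_cohort()], which simulates a source cohort under
#' a proportional-hazards model and draws age-matched case-control sets by
#' incidence-density sampling, so that the conditional-logistic estimand
#' equals `log_odds` (the odds ratio is interpretable as a rate ratio).
#'
#' @param n_sets Number of matched sets (>= 1); each has exactly one case.
#' @param controls_per_set_dist Named numeric vector of probabilities over
#'   the number of controls per set, e.g. `c("1" = 0.5, "2" = 0.5)` (the
#'   study used a variable matching ratio of 1-4 controls).
#' @param age_dist List: `mean`, `sd`, `min`, `max` of a truncated normal age
#'   (years) at diagnosis.
#' @param age_match_window_years Maximum age difference between any two
#'   members of a set (default 0.5 years, i.e. matching to within ±6
#'   months); controls are drawn within half this window of their case.
#' @param covariate_model Named list; each element is
#'   `list(type = "binary", prevalence = p)` or
#'   `list(type = "normal", mean = m, sd = s)`.
#' @param log_odds Named numeric vector of true log odds ratios per unit of
#'   each covariate (names must appear in `covariate_model`).
#' @param age_area_slope Added age trend, in covariate units per year of age
#'   centred at the mean age, applied to every `"normal"` covariate
#'   (emulates the rise of adipocyte area with age). Default 0.
#' @param cohort_size Source-cohort size; default `12 * n_sets`.
#' @param followup_years Administrative censoring horizon (default 15).
#' @param seed Integer seed.
#' @export
cohort_spec <- function(n_sets,
                        controls_per_set_dist = c("1" = 0.5, "2" = 0.5),
                        age_dist = list(mean = 57, sd = 9, min = 35, max = 85),
                        age_match_window_years = 0.5,
                        covariate_model = list(
                          exposed = list(type = "binary", prevalence = 0.3)),
                        log_odds = c(exposed = log(2)),
                        age_area_slope = 0,
                        cohort_size = NULL,
                        followup_years = 15,
                        seed = 1L) {
  stopifnot(n_sets >= 1, age_match_window_years >= 0, followup_years > 0)
  ncd <- as.integer(names(controls_per_set_dist))
  if (any(is.na(ncd)) || any(ncd < 1) || abs(sum(controls_per_set_dist) - 1) > 1e-8)
    stop("controls_per_set_dist must be named probabilities over counts >= 1",
         call. = FALSE)
  for (nm in names(covariate_model)) {
    cv <- covariate_model[[nm]]
    if (identical(cv$type, "binary") &&
        (cv$prevalence <= 0 || cv$prevalence >= 1))
      stop("degenerate covariate '", nm, "': prevalence must be in (0, 1)",
           call. = FALSE)
  }
  if (length(log_odds) && !all(names(log_odds) %in% names(covariate_model)))
    stop("log_odds names must match covariate_model", call. = FALSE)
  structure(list(n_sets = as.integer(n_sets),
                 controls_per_set_dist = controls_per_set_dist,
                 age_dist = age_dist,
                 age_match_window_years = age_match_window_years,
                 covariate_model = covariate_model, log_odds = log_odds,
                 age_area_slope = age_area_slope,
                 cohort_size = cohort_size %||% 12L * as.integer(n_sets),
                 followup_years = followup_years, seed = as.integer(seed)),
            class = "cohort_spec")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate an age-matched nested case-control cohort
#'
#' Simulates `cohort_size` subjects with truncated-normal ages and covariates
#' from `covariate_model`; event times are exponential with hazard
#' `lambda0 * exp(sum(log_odds * x))` under administrative censoring. The
#' earliest `n_sets` events become cases; controls are drawn without
#' replacement from each case's risk set (event-free at the case's event
#' time, age within `age_match_window_years`). A control may later be a case
#' of its own set and may serve several sets, as in incidence-density
#' sampling.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with `set_id`, `patient_id` (source-cohort subject id;
#'   repeats when a subject serves several sets), `is_case`, `age_years`,
#'   and one column per covariate. Exactly one case per set, >= 1 control.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    N <- spec$cohort_size
    ad <- spec$age_dist
    age <- rtruncnorm1(N, ad$mean, ad$sd, ad$min, ad$max)
    X <- purrr::imap(spec$covariate_model, function(cv, nm) {
      v <- switch(cv$type,
                  binary = stats::rbinom(N, 1, cv$prevalence),
                  normal = stats::rnorm(N, cv$mean, cv$sd),
                  stop("unknown covariate type: ", cv$type, call. = FALSE))
      if (identical(cv$type, "normal") && spec$age_area_slope != 0)
        v <- v + spec$age_area_slope * (age - ad$mean)
      v
    })
    eta <- rep(0, N)
    for (nm in names(spec$log_odds))
      eta <- eta + spec$log_odds[[nm]] * X[[nm]]
    # baseline hazard sized so that ~2.2 * n_sets events occur before censoring
    lam0 <- 2.2 * spec$n_sets / (N * mean(exp(eta)) * spec$followup_years)
    tt <- stats::rexp(N, lam0 * exp(eta))
    event <- tt <= spec$followup_years
    time_out <- pmin(tt, spec$followup_years)
    ev_idx <- which(event)[order(tt[event])]
    if (length(ev_idx) < spec$n_sets)
      stop("simulated cohort produced too few events (", length(ev_idx),
           ") for n_sets = ", spec$n_sets,
           "; increase cohort_size or followup_years", call. = FALSE)
    ao <- order(age)                       # age-sorted index for risk-set lookup
    age_sorted <- age[ao]
    w <- spec$age_match_window_years
    m_counts <- as.integer(names(spec$controls_per_set_dist))
    sets <- vector("list", spec$n_sets)
    set_id <- 0L
    # controls within half the window of the case, so that any two members
    # of a set differ in age by at most the full window
    wh <- w / 2
    for (i in ev_idx) {
      if (set_id >= spec$n_sets) break
      lo <- findInterval(age[i] - wh, age_sorted) + 1L
      if (lo > 1L && age_sorted[lo - 1L] >= age[i] - wh) lo <- lo - 1L
      hi <- findInterval(age[i] + wh, age_sorted)
      cand <- if (lo <= hi) ao[lo:hi] else integer(0)
      cand <- cand[cand != i & time_out[cand] > tt[i]]
      if (!length(cand)) next
      m <- if (length(m_counts) == 1L) m_counts else
        sample(m_counts, 1L, prob = spec$controls_per_set_dist)
      ctrl <- if (length(cand) <= m) cand else sample(cand, m)
      set_id <- set_id + 1L
      sets[[set_id]] <- tibble::tibble(
        set_id = set_id, patient_id = c(i, ctrl),
        is_case = c(TRUE, rep(FALSE, length(ctrl))),
        age_years = age[c(i, ctrl)])
    }
    if (set_id < spec$n_sets)
      stop("only ", set_id, " of ", spec$n_sets, " sets could be formed ",
           "(risk sets exhausted); increase cohort_size", call. = FALSE)
    out <- dplyr::bind_rows(sets)
    for (nm in names(X)) out[[nm]] <- X[[nm]][out$patient_id]
    out
  })
}
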