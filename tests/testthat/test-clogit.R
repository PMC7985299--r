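# Conditional logistic regression: closed forms, oracle equivalence,
# identifiability and inference contracts.

test_that("1:1 binary matched data gives the discordant-pair closed form", {
  d <- paired_cohort(n10 = 10, n01 = 5)
  f <- clr_fit(d, "x")
  expect_equal(unname(f$or), 2, tolerance = 1e-8)
  expect_equal(unname(f$beta), log(2), tolerance = 1e-8)
  expect_true(f$converged)
  # concordant pairs carry no information: dropping them changes nothing
  f2 <- clr_fit(paired_cohort(10, 5, n_conc = 0), "x")
  expect_equal(f2$beta, f$beta, tolerance = 1e-8)
})

test_that("fit agrees with survival::clogit on a simulated cohort", {
  skip_if_not_installed("survival")
  co <- generate_cohort(cohort_spec(
    n_sets = 200,
    covariate_model = list(exposed = list(type = "binary", prevalence = 0.3),
                           z = list(type = "normal", mean = 0, sd = 1)),
    log_odds = c(exposed = log(2.5), z = 0.3), seed = 77))
  mine <- clr_fit(co, c("exposed", "z"))
  ref <- survival::coxph(
    survival::Surv(rep(1, nrow(co)), co$is_case) ~ exposed + z +
      survival::strata(set_id), data = co, method = "exact")
  expect_equal(unname(mine$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(mine$loglik, ref$loglik[2], tolerance = 1e-8)
})

test_that("set-constant shifts do not move the estimate (matching absorbs them)", {
  co <- generate_cohort(cohort_spec(n_sets = 150,
                                    log_odds = c(exposed = log(2)), seed = 31))
  f0 <- clr_fit(co, "exposed")
  shifted <- co |>
    dplyr::group_by(set_id) |>
    dplyr::mutate(exposed_shift = exposed + dplyr::cur_group_id() * 3.7) |>
    dplyr::ungroup()
  f1 <- clr_fit(shifted, "exposed_shift")
  expect_equal(unname(f1$beta), unname(f0$beta), tolerance = 1e-8)
})

test_that("non-identifiable and aliased terms are handled explicitly", {
  co <- generate_cohort(cohort_spec(n_sets = 60, seed = 4))
  co$const <- dplyr::pull(dplyr::mutate(
    dplyr::group_by(co, set_id), v = age_years[1]), v)  # set-constant
  expect_error(clr_fit(co, "const"), "non-identifiable")
  co$copy <- co$exposed
  expect_warning(f <- clr_fit(co, c("exposed", "copy")), "aliased")
  expect_equal(f$terms, "exposed")
})

test_that("missing covariates drop whole sets, mirrored in bookkeeping", {
  co <- generate_cohort(cohort_spec(n_sets = 100, seed = 12))
  co$exposed[co$set_id == 7][1] <- NA
  f <- clr_fit(co, "exposed")
  expect_equal(f$n_sets_used, 99L)
  expect_equal(f$n_sets_dropped, 1L)
  expect_false("7" %in% f$set_ids_used)
})

test_that("Wald CI brackets the OR and loglik is non-positive", {
  co <- generate_cohort(cohort_spec(n_sets = 120, seed = 8))
  f <- clr_fit(co, "exposed")
  expect_true(all(f$ci_low < f$or & f$or < f$ci_high))
  expect_lte(f$loglik, 0)
  expect_lte(f$loglik_null, 0)
  expect_gte(f$loglik, f$loglik_null)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "or", "conf.low",
                     "conf.high", "statistic", "p.value"))
  expect_equal(glance(f)$df, 1)
})

test_that("likelihood-ratio test contracts hold", {
  co <- generate_cohort(cohort_spec(
    n_sets = 150,
    covariate_model = list(exposed = list(type = "binary", prevalence = 0.3),
                           z = list(type = "normal", mean = 0, sd = 1)),
    log_odds = c(exposed = log(2)), seed = 91))
  f1 <- clr_fit(co, "exposed")
  f2 <- clr_fit(co, c("exposed", "z"))
  lrt <- likelihood_ratio_test(f1, f2)
  expect_equal(lrt$df, 1)
  expect_gte(lrt$statistic, 0)
  expect_true(lrt$p_value >= 0 && lrt$p_value <= 1)
  # adding an exact copy: the copy is dropped, statistic 0, p = 1
  co$copy <- co$exposed
  expect_warning(f3 <- clr_fit(co, c("exposed", "copy")), "aliased")
  lrt0 <- likelihood_ratio_test(f1, f3)
  expect_equal(lrt0$statistic, 0, tolerance = 1e-10)
  expect_equal(lrt0$df, 0)
  expect_equal(lrt0$p_value, 1)
  # different data: error
  co_b <- generate_cohort(cohort_spec(n_sets = 50, seed = 92))
  expect_error(likelihood_ratio_test(clr_fit(co_b, "exposed"), f2),
               "different matched sets")
})

test_that("crude OR from pooled margins differs from the conditional estimate", {
  # pooled 2x2 margins (case/control x high/low) give the crude OR
  # (96*36)/(10*128); the matched-set estimate is a different quantity
  crude_from_margins <- (96 * 36) / (10 * 128)
  expect_equal(crude_from_margins, 2.7, tolerance = 1e-12)
  # on simulated age-matched data with an age-linked exposure, the two differ
  co <- generate_cohort(cohort_spec(
    n_sets = 400,
    covariate_model = list(area = list(type = "normal", mean = 6, sd = 1)),
    log_odds = c(area = 0.4), age_area_slope = 0.08,
    cohort_size = 8000, seed = 55))
  cond <- unname(clr_fit(co, "area")$beta)
  crude <- unname(coef(glm(is_case ~ area, family = binomial, data = co))["area"])
  expect_gt(abs(crude - cond), 0.02)
})

test_that("Wald CI widens on average as sets are removed", {
  widths <- vapply(1:12, function(i) {
    co <- generate_cohort(cohort_spec(n_sets = 300, seed = 200 + i,
                                      log_odds = c(exposed = log(2))))
    f_all <- clr_fit(co, "exposed")
    f_half <- clr_fit(dplyr::filter(co, set_id <= 150), "exposed")
    c(log(f_all$ci_high / f_all$ci_low), log(f_half$ci_high / f_half$ci_low))
  }, numeric(2))
  expect_lt(mean(widths[1, ]), mean(widths[2, ]))
})
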