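# Expected cumulative incidence under competing mortality.

# small local group -> column pivot
tidyr_free_pivot <- function(cur) {
  grs <- unique(cur$group)
  out <- data.frame(t = cur$t[cur$group == grs[1]])
  for (gr in grs) out[[gr]] <- cur$ci[cur$group == gr]
  out
}

test_that("constant hazards reproduce the closed-form competing-risk CI", {
  rates <- generate_rate_table(0.01, 0.02, age_range = c(50, 70))
  cur <- expected_cumulative_incidence(rates, start_age = 55,
                                       horizon_years = 10)
  # closed form: (lambda/(lambda+mu)) * (1 - exp(-(lambda+mu) t))
  expect_equal(cur$ci[cur$t == 10], (1 / 3) * (1 - exp(-0.3)),
               tolerance = 1e-9)
  expect_equal(cur$s[cur$t == 10], exp(-0.3), tolerance = 1e-9)
  expect_equal(cur$ci[1], 0)
})

test_that("zero mortality reduces to 1 - exp(-lambda t)", {
  rates <- generate_rate_table(0.015, 0, age_range = c(40, 80))
  cur <- expected_cumulative_incidence(rates, 50, 20)
  expect_equal(cur$ci, 1 - exp(-0.015 * cur$t), tolerance = 1e-9)
  expect_true(all(cur$cum_mort == 0))
})

test_that("annual steps match a fine-grid integration on piecewise rates", {
  rates <- generate_rate_table(0.004, 0.01, age_range = c(50, 90),
                               incidence_shape = list(family = "loglinear",
                                                      slope = 0.06),
                               mortality_shape = list(family = "gompertz",
                                                      rate = 0.09))
  coarse <- expected_cumulative_incidence(rates, 57, 15, step_years = 1)
  fine <- expected_cumulative_incidence(rates, 57, 15, step_years = 0.01)
  for (tt in c(5, 10, 15)) {
    expect_equal(coarse$ci[abs(coarse$t - tt) < 1e-9],
                 fine$ci[abs(fine$t - tt) < 1e-9], tolerance = 1e-4)
  }
})

test_that("probability contracts: monotone CI, bounded totals, zero rates", {
  rates <- generate_rate_table(0.02, 0.05, age_range = c(50, 90),
                               mortality_shape = list(family = "gompertz",
                                                      rate = 0.08))
  cur <- expected_cumulative_incidence(rates, 52, 30)
  expect_true(all(diff(cur$ci) >= 0))
  expect_true(all(cur$ci + cur$cum_mort <= 1 + 1e-12))
  expect_true(all(abs(cur$ci + cur$cum_mort + cur$s - 1) < 1e-12))
  z <- expected_cumulative_incidence(generate_rate_table(0, 0), 55, 10)
  expect_true(all(z$ci == 0) && all(z$s == 1))
})

test_that("rate-table validation and horizon errors", {
  expect_error(generate_rate_table(-0.01, 0.02), ">= 0")
  rates <- generate_rate_table(0.01, 0.02, age_range = c(50, 60))
  expect_error(expected_cumulative_incidence(rates, 55, 20), "beyond")
  expect_error(expected_cumulative_incidence(rates, 55, 5, step_years = -1),
               "> 0")
})

test_that("identical rate ratios collapse group curves onto the marginal", {
  rates <- generate_rate_table(0.012, 0.02, age_range = c(50, 80))
  groups <- tibble::tibble(group = c("a", "b"), prevalence = c(0.4, 0.6),
                           rate_ratio = c(1, 1))
  cur <- group_specific_incidence(rates, groups, 55, 15)
  marg <- dplyr::filter(cur, group == ".marginal")
  for (gr in c("a", "b")) {
    expect_equal(dplyr::filter(cur, group == gr)$ci, marg$ci, tolerance = 1e-12)
  }
})

test_that("prevalence-weighted group curves reproduce the marginal curve", {
  rates <- generate_rate_table(0.01, 0.02, age_range = c(50, 80))
  groups <- tibble::tibble(group = c("low", "high"), prevalence = c(0.8, 0.2),
                           rate_ratio = c(1, 3))
  cur <- group_specific_incidence(rates, groups, 55, 15)
  wide <- tidyr_free_pivot(cur)
  mix <- 0.8 * wide$low + 0.2 * wide$high
  expect_true(all(abs(mix - wide$.marginal) < 1e-3))
})

test_that("raising a group's rate ratio raises its whole curve", {
  rates <- generate_rate_table(0.01, 0.015, age_range = c(50, 80))
  g1 <- tibble::tibble(group = c("a", "b"), prevalence = c(0.7, 0.3),
                       rate_ratio = c(1, 2))
  g2 <- tibble::tibble(group = c("a", "b"), prevalence = c(0.7, 0.3),
                       rate_ratio = c(1, 4))
  c1 <- dplyr::filter(group_specific_incidence(rates, g1, 55, 15), group == "b")
  c2 <- dplyr::filter(group_specific_incidence(rates, g2, 55, 15), group == "b")
  expect_true(all(c2$ci[-1] > c1$ci[-1]))
})

test_that("group validation errors", {
  rates <- generate_rate_table(0.01, 0.02)
  bad <- tibble::tibble(group = "a", prevalence = 0.8, rate_ratio = 2)
  expect_error(group_specific_incidence(rates, bad, 55, 10), "sum to 1")
  bad2 <- tibble::tibble(group = c("a", "b"), prevalence = c(0.5, 0.5),
                         rate_ratio = c(1, -2))
  expect_error(group_specific_incidence(rates, bad2, 55, 10), "> 0")
})

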