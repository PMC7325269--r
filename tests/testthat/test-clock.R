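test_that("scale factors follow i/(i+1) with an unscaled tip period", {
  expect_equal(scale_factor(5, 5), 1)
  expect_equal(scale_factor(2, 5), 0.67)
  expect_equal(scale_factor(4, 5), 0.80)
  expect_equal(scale_factor(2, 5, "exact"), 2 / 3)
  expect_error(scale_factor(1, 5), "2 <= i <= n")
  expect_error(scale_factor(6, 5), "2 <= i <= n")

  # non-decreasing in i, equal to 1 only at the tip period
  f <- vapply(2:10, scale_factor, numeric(1), n = 10, rounding = "exact")
  expect_true(all(diff(f) >= 0))
  expect_equal(which(f == 1), 9)
})

test_that("period ages reproduce the hand-calculation rounding chain", {
  r2 <- period_age(1.5, 2, 5)
  expect_equal(r2$scaled_rate, 1.44e-4)
  expect_equal(r2$years_per_mutation, 6944)
  expect_equal(r2$years, 10416)

  r3 <- period_age(2, 3, 5)
  expect_equal(r3$scaled_rate, 1.61e-4)
  expect_equal(r3$years_per_mutation, 6211)
  expect_equal(r3$years, 12422)

  r5 <- period_age(1, 5, 5, rate_model(rounding = "exact"))
  expect_equal(r5$years, 4651)
})

test_that("the worked five-lineage example reproduces cell by cell", {
  fit <- rho_age(worked_example_table())
  pp <- fit$per_period
  expect_equal(pp$rho, c(1.5, 2, 0.5, 1))
  expect_equal(pp$factor, c(0.67, 0.75, 0.80, 1))
  expect_equal(pp$scaled_rate, c(1.44e-4, 1.61e-4, 1.72e-4, 2.15e-4))
  expect_equal(pp$years_per_mutation, c(6944, 6211, 5814, 4651))
  expect_equal(pp$years, c(10416, 12422, 2907, 4651))
  expect_equal(fit$age_years, 30396)
  expect_equal(fit$sd_years, 5513)
})

test_that("exact mode matches a term-by-term oracle and stays within 0.5%", {
  fit <- rho_age(worked_example_table(), rate_model(rounding = "exact"))
  oracle <- 1.5 * 4651 / (2 / 3) + 2 * 4651 / (3 / 4) +
    0.5 * 4651 / (4 / 5) + 1 * 4651
  expect_equal(fit$age_years, oracle, tolerance = 1e-12)
  expect_lt(abs(fit$age_years - 30396) / 30396, 0.005)
})

test_that("scaling is inert on a single tip period (star table)", {
  tab <- period_table(5, 15)  # star: all mutations in the tip period
  scaled <- rho_age(tab, rate_model(rounding = "exact"))
  unscaled <- rho_age(tab, rate_model(rounding = "exact"), scaling = "none")
  expect_equal(scaled$age_years, 3 * 4651)
  expect_equal(scaled$age_years, unscaled$age_years)
})

test_that("scaled exact age exceeds unscaled iff internal periods mutate", {
  rate <- rate_model(rounding = "exact")
  with_internal <- period_table(c(2, 4), c(1, 3))
  expect_gt(rho_age(with_internal, rate)$age_years,
            rho_age(with_internal, rate, scaling = "none")$age_years)
  tips_only <- period_table(c(2, 4), c(0, 6))
  expect_equal(rho_age(tips_only, rate)$age_years,
               rho_age(tips_only, rate, scaling = "none")$age_years)
})

test_that("the Poisson-kiloyear rule reproduces published sd and CI values", {
  cases <- rbind(c(30396, 5513), c(22277, 4720), c(112829, 10622),
                 c(165610, 12869), c(37701, 6140))
  for (k in seq_len(nrow(cases)))
    expect_equal(unname(poisson_kyr_uncertainty(cases[k, 1])["sd_years"]),
                 cases[k, 2])

  u <- poisson_kyr_uncertainty(37701)
  expect_equal(unname(u["ci95_low"]), 25667)
  expect_equal(unname(u["ci95_high"]), 49735)
  u <- poisson_kyr_uncertainty(165610)
  expect_equal(unname(u["ci95_low"]), 140387)
  expect_equal(unname(u["ci95_high"]), 190833)

  expect_equal(unname(poisson_kyr_uncertainty(0)), c(0, 0, 0))
  expect_error(poisson_kyr_uncertainty(-1), "non-negative")
})

test_that("compound-Poisson sd matches the closed form and Monte Carlo", {
  rate <- rate_model(rounding = "exact")
  # single unscaled period, gamma = 5 at i = n = 5
  sd1 <- compound_poisson_uncertainty(period_table(5, 5), rate)
  expect_equal(sd1, sqrt(5) * 4651 / 5, tolerance = 1e-12)

  expect_equal(compound_poisson_uncertainty(
    period_table(c(2, 5), c(0, 0)), rate), 0)

  # worked example, table-mode years-per-mutation: Monte Carlo resampling of
  # per-period Poisson counts agrees with the propagated closed form
  tab <- worked_example_table()
  sd_cf <- compound_poisson_uncertainty(tab, rate_model())
  ypm <- c(6944, 6211, 5814, 4651)
  set.seed(7)
  draws <- vapply(seq_len(nrow(tab)), function(k)
    stats::rpois(1e5, tab$mutations[k]) * ypm[k] / tab$lineages[k],
    numeric(1e5))
  expect_equal(stats::sd(rowSums(draws)), sd_cf, tolerance = 0.01)
})

test_that("fixation probability tracks the size ratio and stays in (0, 1]", {
  expect_equal(fixation_probability(1000, 2000), 2 / 1000)
  expect_equal(fixation_probability(1000, 500), 1 / 2000)
  expect_equal(fixation_probability(1000, 1000), 1 / 1000)
  expect_warning(q <- fixation_probability(1, 10), "clamped")
  expect_equal(q, 1)
  expect_error(fixation_probability(0, 10), "positive")
})

test_that("fluctuating-size substitution rate scales mu by the size ratio", {
  expect_equal(fluctuating_substitution_rate(1000, 1000, 2.15e-4), 2.15e-4)
  expect_equal(fluctuating_substitution_rate(1000, 2000, 2.15e-4), 4.30e-4)
  expect_equal(fluctuating_substitution_rate(1000, 2000, 2.15e-4,
                                             backward = TRUE), 2.15e-4 / 2)
  expect_error(fluctuating_substitution_rate(1000, -1, 2.15e-4), "positive")
})

test_that("rate models derive the year scalar from per-site rates", {
  r <- rate_model(mu_per_site_per_year = 1.3e-8)
  expect_equal(r$years_per_mutation, 1 / (1.3e-8 * 16569))
  expect_equal(rate_model()$years_per_mutation, 4651)
  expect_error(rate_model(-1), "years_per_mutation > 0")
})
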