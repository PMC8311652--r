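test_that("cohort means report the worked example correctly", {
  obs <- mean_cumulative_citations(c(21, 528))
  expect_equal(obs$mean, 274.5)
  expect_equal(obs$reported, 274)
  expect_equal(mean_cumulative_citations(c(7))$mean, 7)
  expect_equal(mean_cumulative_citations(c(0, 0, 0))$mean, 0)
  expect_error(mean_cumulative_citations(numeric()),
               class = "undefined_observation")
})

test_that("the citation-expectation model reproduces the worked example", {
  expect_equal(round(expected_total_citations(274.5, 22, 5.4)), 279)
  expect_equal(round(expected_total_citations(274.5, 22, 7.1)), 287)
  expect_equal(expected_total_citations(0, 10, 5.4), 0)
  expect_error(expected_total_citations(10, 0, 5.4), class = "domain_error")
  expect_error(expected_total_citations(10, 5, -1), class = "domain_error")
})

test_that("the expectation is monotone in its arguments and bounded below by the observation", {
  nbar <- 100
  dts <- c(1, 2, 5, 10, 30)
  vals <- vapply(dts, function(dt)
    expected_total_citations(nbar, dt, 5.4), numeric(1))
  expect_true(all(diff(vals) < 0))                 # decreasing in delta-t
  betas <- c(1, 3, 5.4, 7.1, 12)
  vals_b <- vapply(betas, function(b)
    expected_total_citations(nbar, 8, b), numeric(1))
  expect_true(all(diff(vals_b) > 0))               # increasing in beta
  expect_true(all(vals >= nbar) && all(vals_b >= nbar))
  # saturation limit: expected -> observed
  expect_equal(expected_total_citations(nbar, 1e6, 5.4), nbar,
               tolerance = 1e-6)
})

test_that("citation trend combines observed means and expected curves per year", {
  corpus <- data.frame(year = c(1999, 1999, 2005),
                       cumulative_citations = c(21, 528, 40))
  tr <- citation_trend(corpus, query_year = 2021)
  row99 <- tr[tr$year == 1999, ]
  expect_equal(row99$observed_mean, 274.5)
  expect_equal(row99$observed_reported, 274)
  expect_equal(round(row99$expected_bio), 279)
  expect_equal(nrow(tr), 2)      # years without publications omitted
  # planted-accrual corpus: expected curve recovers the planted total
  gen <- generate_publication_corpus(
    schedule = c("1996" = 3, "2001" = 4, "2008" = 5), n_background = 0,
    total_citations = 150, beta = 5.4, noise = "none", seed = 9,
    dir = withr::local_tempdir())
  corpus2 <- read_corpus(gen$path)
  tr2 <- citation_trend(corpus2, betas = c(bio = 5.4), query_year = 2021)
  expect_equal(tr2$expected_bio, rep(150, 3), tolerance = 0.005)
})

test_that("fit_beta recovers planted accrual parameters", {
  t <- 1:20
  # noiseless series: exact recovery for both discipline presets
  for (b in c(5.4, 7.1)) {
    fit <- fit_beta(t, 200 * (1 - exp(-t / b)))
    expect_equal(fit$beta, b, tolerance = 1e-6)
    expect_equal(fit$N, 200, tolerance = 1e-6)
  }
  expect_error(fit_beta(1:2, c(1, 2)), class = "fit_error")
  expect_error(fit_beta(t, rep(5, 20)), class = "fit_error")
  expect_warning(fit_beta(1:5, c(1, 5, 3, 8, 9)), class = "fit_warning")
})

test_that("beta is recovered within 10% from 200 noisy simulated papers", {
  gen <- generate_publication_corpus(
    schedule = stats::setNames(rep(10, 20), 2000:2019), n_background = 0,
    total_citations = 120, beta = 5.4, noise = "poisson", seed = 2021,
    dir = withr::local_tempdir())
  corpus <- read_corpus(gen$path)
  expect_equal(nrow(corpus), 200)
  agg <- aggregate(cumulative_citations ~ year, corpus, mean)
  dt <- gen$truth$query_year - agg$year
  # noisy per-year means need not be monotone; the warning is expected
  fit <- suppressWarnings(fit_beta(dt, agg$cumulative_citations))
  expect_lt(abs(fit$beta - 5.4) / 5.4, 0.10)
})

test_that("country normalization divides hits by the configured denominator", {
  pop <- data.frame(country = rep(c("X", "Y"), each = 2),
                    year = rep(c(2000, 2001), 2),
                    population = c(1e6, 1e6, 2e6, 2e6))
  out <- normalize_country_counts(c(X = 10, Y = 10), pop, "per_capita")
  expect_equal(out$normalized_rate, c(1e-5, 5e-6))
  expect_equal(out$country, c("X", "Y"))     # ranked by rate

  nat <- data.frame(country = c("X", "Y"), n_publications = c(100, 1000))
  out2 <- normalize_country_counts(c(X = 10, Y = 10), nat, "per_output")
  expect_equal(out2$normalized_rate[out2$country == "X"], 0.1)
  expect_equal(out2$normalized_rate[out2$country == "Y"], 0.01)

  expect_warning(
    out3 <- normalize_country_counts(c(X = 10, Z = 5), pop, "per_capita"),
    class = "missing_denominator")
  expect_false("Z" %in% out3$country)
})
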