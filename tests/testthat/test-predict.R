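fit_once <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_panel(n_persons = 300L, sigma_u = 0.5,
                         surface = "age_quadratic", seed = 61)
      cache <<- apc_fit(sim$panel, variant = "smooth")
    }
    cache
  }
})

test_that("population mean relates to the median person by the lognormal factor", {
  f <- fit_once()
  med <- reference_surface(f, ndraws = 100L)
  pop <- reference_surface(f, estimand = "population_mean", ndraws = 100L)
  expect_equal(pop$estimate, med$estimate * exp(f$sigma_u^2 / 2),
               tolerance = 1e-10)
  # Jensen direction and identical domain rankings
  expect_true(all(pop$estimate >= med$estimate))
  expect_identical(order(pop$estimate), order(med$estimate))

  # Monte-Carlo oracle for the lognormal moment at one grid point
  set.seed(4)
  u <- rnorm(100000L, 0, 0.5)
  expect_lt(abs(3 * mean(exp(u)) - 3 * exp(0.125)), 1e-2)
})

test_that("without frailty the mean and median-person surfaces coincide", {
  sim <- small_panel(n_persons = 100L, sigma_u = 0, seed = 3)
  f <- apc_fit(sim$panel, variant = "pooled", covariates = character(0),
               sigma_u = 0)
  med <- reference_surface(f, ndraws = 50L)
  pop <- reference_surface(f, estimand = "population_mean", ndraws = 50L)
  expect_identical(med$estimate, pop$estimate)
})

test_that("tail proportions follow the Poisson cmf and grow with frailty", {
  # closed form at rate 5 without frailty
  sim <- small_panel(n_persons = 100L, sigma_u = 0, alpha = log(5), seed = 5)
  f0 <- apc_fit(sim$panel, variant = "pooled", covariates = character(0),
                sigma_u = 0)
  pr0 <- reference_surface(f0, estimand = "proportion_le_k", k_le = 2L,
                           ndraws = 50L)
  rate <- exp(coef(f0)[[1L]])
  expect_equal(unique(round(pr0$estimate, 12)),
               round(exp(-rate) * (1 + rate + rate^2 / 2), 12))
  expect_equal(ppois(2, 5), exp(-5) * (1 + 5 + 12.5), tolerance = 1e-12)

  # at a median rate of five, frailty inflates the probability of having
  # no more than two visits relative to the plain Poisson value
  sim5 <- small_panel(n_persons = 400L, sigma_u = 0.5, alpha = log(5),
                      seed = 7)
  f5 <- apc_fit(sim5$panel, variant = "pooled")
  med5 <- reference_surface(f5, ndraws = 50L)
  pr5 <- reference_surface(f5, estimand = "proportion_le_k", k_le = 2L,
                           ndraws = 50L)
  expect_true(all(pr5$estimate > ppois(2, med5$estimate)))

  # monotone: non-decreasing in k, non-increasing in the rate
  f <- fit_once()
  grid <- surface_grid(f)[1:20, ]
  med <- reference_surface(f, grid, ndraws = 50L)
  pr_frail <- reference_surface(f, grid, estimand = "proportion_le_k",
                                k_le = 2L, ndraws = 50L)
  pr3 <- reference_surface(f, grid, estimand = "proportion_le_k", k_le = 3L,
                           ndraws = 50L)
  expect_true(all(pr3$estimate >= pr_frail$estimate))
  ord <- order(med$estimate)
  expect_true(all(diff(pr_frail$estimate[ord]) <= 1e-12))
})

test_that("interval bounds bracket estimates and respect the level", {
  f <- fit_once()
  s <- reference_surface(f, ndraws = 400L)
  expect_true(all(s$lower <= s$estimate + 1e-8))
  expect_true(all(s$estimate <= s$upper + 1e-8))
  expect_true(all(s$estimate > 0))
  rr <- covariate_relative_rates(f)
  expect_true(all(rr$lower < rr$rr & rr$rr < rr$upper))
})

test_that("no extrapolation beyond the fitted rectangle", {
  f <- fit_once()
  bad <- data.frame(birth_year = 1900, year = 2010)
  expect_error(reference_surface(f, bad), "boundary")
})

test_that("self-contrast is zero and a constructed offset is recovered", {
  f <- fit_once()
  ct0 <- contrast(f, f, ndraws = 200L)
  expect_true(all(ct0$difference == 0))
  expect_true(all(ct0$lower <= 0 & ct0$upper >= 0))

  # simulate a second stratum whose log-rate is 0.3 higher everywhere
  sc_m <- apc_scenario(n_persons = 700L, sigma_u = 0.4, surface = "flat",
                       alpha = log(3), seed = 101)
  sc_f <- apc_scenario(n_persons = 700L, sigma_u = 0.4, surface = "flat",
                       alpha = log(3) + 0.3, seed = 202)
  fm <- apc_fit(simulate_panel(sc_m)$panel, variant = "smooth")
  ff <- apc_fit(simulate_panel(sc_f)$panel, variant = "smooth")
  ct <- contrast(ff, fm, ndraws = 400L)
  target <- 3 * (exp(0.3) - 1)
  expect_lt(median(abs(ct$difference - target)), 0.35)
  # most intervals exclude zero under a true offset
  expect_gt(mean(ct$lower > 0), 0.7)

  # no offset: roughly nominal share of intervals excludes zero
  sc_f0 <- apc_scenario(n_persons = 700L, sigma_u = 0.4, surface = "flat",
                        alpha = log(3), seed = 303)
  ff0 <- apc_fit(simulate_panel(sc_f0)$panel, variant = "smooth")
  ct0b <- contrast(ff0, fm, ndraws = 400L)
  expect_lt(mean(ct0b$lower > 0 | ct0b$upper < 0), 0.35)
})

test_that("surface export round-trips exactly and extracts cohorts", {
  f <- fit_once()
  s <- reference_surface(f, ndraws = 50L)
  path <- tempfile(fileext = ".csv")
  export_surface(s, path)
  back <- read.csv(path)
  expect_identical(back$estimate, s$estimate)
  expect_identical(back$lower, s$lower)
  expect_equal(nrow(back), nrow(s))

  export_surface(s, path, cohorts = 1975L)
  sel <- read.csv(path)
  expect_true(all(sel$birth_year == 1975L))
  expect_equal(nrow(sel), sum(s$birth_year == 1975L))
})
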