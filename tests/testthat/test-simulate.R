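test_that("the degenerate scenario is iid Poisson with the stated mean", {
  sc <- apc_scenario(n_persons = 800L, sigma_u = 0, surface = "flat",
                     alpha = log(3),
                     employment_stationary = c(employed = 1, unemployed = 0,
                                               nilf = 0),
                     missing_wave_prob = 0, seed = 99)
  sim <- simulate_panel(sc)
  n <- nrow(sim$panel)
  expect_gt(n, 10000L)
  se <- sqrt(3 / n)
  expect_lt(abs(mean(sim$panel$count) - 3), 3 * se)
  # conditional dispersion: all mu identical here, so var ~ mean
  expect_lt(abs(var(sim$panel$count) / mean(sim$panel$count) - 1), 0.05)
  expect_true(all(abs(sim$panel$mu - 3) < 1e-12))
})

test_that("simulation is deterministic given the seed and leaves the RNG alone", {
  sc <- apc_scenario(n_persons = 50L, seed = 7)
  set.seed(123); x_before <- runif(1)
  sim1 <- simulate_panel(sc)
  sim2 <- simulate_panel(sc)
  expect_identical(sim1$panel, sim2$panel)
  expect_identical(sim1$truth$u, sim2$truth$u)
  set.seed(123); expect_identical(runif(1), x_before)
})

test_that("lognormal frailty inflates the population mean by exp(sigma^2/2)", {
  sc <- apc_scenario(n_persons = 4000L, sigma_u = 0.5, surface = "flat",
                     alpha = log(2),
                     employment_stationary = c(employed = 1, unemployed = 0,
                                               nilf = 0),
                     missing_wave_prob = 0, seed = 41)
  sim <- simulate_panel(sc)
  target <- 2 * exp(0.5^2 / 2)
  n <- nrow(sim$panel)
  expect_gt(n, 50000L)
  # counts within a person are correlated; SE via person-level means
  pm <- tapply(sim$panel$count, sim$panel$person_id, mean)
  se <- sd(pm) / sqrt(length(pm))
  expect_lt(abs(mean(sim$panel$count) - target), 3 * se)
  # marginal overdispersion must be visible
  expect_gt(var(sim$panel$count), 1.2 * mean(sim$panel$count))
})

test_that("built-in surfaces have their advertised shapes", {
  expect_equal(builtin_surface("flat")(1960, 2010), 0)

  g <- builtin_surface("age_linear", slope = 0.03)
  C <- c(1955, 1970, 1985)
  expect_equal(g(C, 2011) - g(C, 2010), rep(0.03, 3L))
  # depends on (C, t) only through age
  expect_equal(g(1960, 2010), g(1950, 2000))

  gu <- builtin_surface("u_shape")
  yrs <- 2002:2016
  vals <- gu(rep(1970, length(yrs)), yrs)
  m <- which.min(vals)
  expect_gt(m, 1L)
  expect_lt(m, length(yrs))

  expect_error(builtin_surface("banana"), "available")
})

test_that("employment dynamics follow the configured stationary mix", {
  sc <- apc_scenario(n_persons = 2000L, seed = 3)
  sim <- simulate_panel(sc)
  frac <- prop.table(table(sim$panel$employment_status))
  expect_lt(abs(frac[["employed"]] - 0.94), 0.03)
})

test_that("panel_to_records round-trips counts and honours construction rules", {
  sim <- small_panel(n_persons = 30L, seed = 17, perinatal_eligible = TRUE,
                     perinatal_rate = 0.2)
  recs <- panel_to_records(sim$panel, gap_days = 1, seed = 9)
  sv <- panel_to_survey(sim$panel)
  panel2 <- build_panel(recs, sv, gap_days = 1)
  key1 <- paste(sim$panel$person_id, sim$panel$year)
  key2 <- paste(panel2$person_id, panel2$year)
  expect_setequal(key1, key2)
  expect_equal(panel2$count, sim$panel$count[match(key2, key1)])

  # zero-count person-years emit no GP records
  zero <- sim$panel[sim$panel$count == 0 & !sim$panel$perinatal, ]
  if (nrow(zero)) {
    gp <- recs[recs$item_code %in% default_gp_items(), ]
    ry <- as.integer(substr(gp$service_date, 1L, 4L))
    expect_false(any(paste(gp$person_id, ry) %in%
                       paste(zero$person_id, zero$year)))
  }

  # perinatal rows emit at least one code in the peri-natal range that year
  peri <- sim$panel[sim$panel$perinatal, ]
  ry <- as.integer(substr(recs$service_date, 1L, 4L))
  inrange <- recs$item_code >= 16400L & recs$item_code <= 16573L
  for (i in seq_len(nrow(peri))) {
    expect_true(any(inrange & recs$person_id == peri$person_id[i] &
                      ry == peri$year[i]))
  }
})

test_that("scenario validation rejects out-of-range parameters", {
  expect_error(apc_scenario(sigma_u = -0.1))
  expect_error(apc_scenario(missing_wave_prob = 1.4))
  expect_error(apc_scenario(employment_stationary = c(employed = 0.5,
                                                      unemployed = 0.2,
                                                      nilf = 0.2)),
               "summing to 1")
})
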