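test_that("intercept-only pooled fit without frailty is the closed-form Poisson MLE", {
  sim <- small_panel(n_persons = 80L, sigma_u = 0, seed = 3)
  f <- apc_fit(sim$panel, variant = "pooled", covariates = character(0),
               sigma_u = 0)
  expect_equal(unname(coef(f)[1L]), log(mean(sim$panel$count)),
               tolerance = 1e-9)
  # score identity: fitted total equals observed total
  expect_equal(sum(fitted(f)), sum(sim$panel$count), tolerance = 1e-6)
  expect_true(f$converged)
})

test_that("pooled fit with covariates matches glm() exactly", {
  sim <- small_panel(n_persons = 120L, sigma_u = 0, seed = 5)
  f <- apc_fit(sim$panel, variant = "pooled", sigma_u = 0)
  g <- glm(count ~ I(employment_status == "nilf") +
             I(employment_status == "unemployed"),
           family = poisson, data = sim$panel)
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-7)
})

test_that("frailty and covariate estimates recover simulation truth at moderate n", {
  sim <- small_panel(n_persons = 800L, sigma_u = 0.5, surface = "flat",
                     seed = 19)
  f <- apc_fit(sim$panel, variant = "pooled")
  expect_true(f$converged)
  expect_lt(abs(f$sigma_u - 0.5), 0.08)
  expect_lt(abs(coef(f)[["nilf"]] - log(1.12)), 0.15)
  # person effects shrink towards zero but correlate strongly with truth
  expect_gt(cor(f$u, sim$truth$u[names(f$u)]), 0.8)
})

test_that("conditional likelihoods respect model nesting at matched variances", {
  sim <- small_panel(n_persons = 250L, surface = "age_quadratic", seed = 23)
  fp <- apc_fit(sim$panel, variant = "pooled")
  fd <- apc_fit(sim$panel, variant = "domain_re")
  fc <- apc_fit(sim$panel, variant = "smooth_plus_domain_re",
                sigma_v = fd$sigma_v)
  expect_lte(fp$loglik_conditional, fd$loglik_conditional + 1e-6)
  expect_lte(fd$loglik_conditional, fc$loglik_conditional + 1e-6)
})

test_that("fitted surfaces are equivariant under a common cohort/period shift", {
  sim <- small_panel(n_persons = 200L, surface = "age_quadratic", seed = 29)
  f1 <- apc_fit(sim$panel, variant = "smooth", k = c(6L, 6L))
  shifted <- sim$panel
  shifted$birth_year <- shifted$birth_year + 500L
  shifted$year <- shifted$year + 500L
  f2 <- apc_fit(shifted, variant = "smooth", k = c(6L, 6L))
  g1 <- surface_grid(f1)
  s1 <- reference_surface(f1, g1, ndraws = 50L)
  g2 <- g1; g2$birth_year <- g2$birth_year + 500L; g2$year <- g2$year + 500L
  s2 <- reference_surface(f2, g2, ndraws = 50L)
  expect_equal(s1$estimate, s2$estimate, tolerance = 1e-4)
})

test_that("a null surface is shrunk towards flat", {
  sim <- small_panel(n_persons = 600L, surface = "flat", seed = 37)
  f <- apc_fit(sim$panel, variant = "smooth")
  s <- reference_surface(f, ndraws = 50L)
  # log-scale deviation of the fitted surface from the global level
  dev <- log(s$estimate) - mean(log(s$estimate))
  expect_lt(max(abs(dev)), 0.15)
})

test_that("degenerate inputs and bad requests raise errors", {
  sim <- small_panel(n_persons = 30L, seed = 2)
  zero <- sim$panel; zero$count <- 0L
  expect_error(apc_fit(zero), "zero")
  expect_error(apc_fit(sim$panel, covariates = "perinatal"), "perinatal")
  expect_error(apc_fit(sim$panel, covariates = "income"))
})

test_that("laplace and mcmc backends agree on fixed effects for a small panel", {
  sim <- small_panel(n_persons = 150L, surface = "age_linear", seed = 47)
  fl <- apc_fit(sim$panel, variant = "smooth", k = c(5L, 5L))
  fm <- apc_fit(sim$panel, variant = "smooth", k = c(5L, 5L),
                backend = "mcmc",
                control = apc_control(mcmc_iter = 1200L, mcmc_burnin = 600L,
                                      mcmc_chains = 2L, seed = 4L))
  expect_lt(max(abs(coef(fl) - coef(fm))), 0.05)
  expect_lt(abs(fl$sigma_u - fm$sigma_u), 0.05)
  # predictive densities from the two representations are close
  rows <- sim$panel[seq_len(20L), ]
  lp_l <- log_pointwise_density(fl, rows)
  lp_m <- log_pointwise_density(fm, rows, allow_unconverged = TRUE)
  expect_lt(mean(abs(lp_l - lp_m)), 0.05)
  expect_lt(max(abs(lp_l - lp_m)), 0.3)
})

test_that("print, summary and basic methods run", {
  sim <- small_panel(n_persons = 60L, seed = 53)
  f <- apc_fit(sim$panel, variant = "pooled")
  expect_output(print(f), "Hierarchical Poisson")
  expect_output(print(summary(f)), "relative rates")
  expect_length(residuals(f), nrow(sim$panel))
  expect_equal(dim(simulate(f, nsim = 2L, seed = 1L)),
               c(nrow(sim$panel), 2L))
  expect_equal(predict(f, sim$panel[1:3, ], type = "link"),
               log(predict(f, sim$panel[1:3, ])))
  ll <- logLik(f)
  expect_s3_class(ll, "logLik")
})

test_that("the Laplace engine agrees with an independent GAMM implementation", {
  sim <- small_panel(n_persons = 250L, sigma_u = 0.5,
                     surface = "age_quadratic", seed = 91)
  pan <- sim$panel
  f <- apc_fit(pan, variant = "smooth")

  pan$pid <- factor(pan$person_id)
  pan$nilf <- as.numeric(pan$employment_status == "nilf")
  pan$unemp <- as.numeric(pan$employment_status == "unemployed")
  g <- mgcv::gam(count ~ nilf + unemp +
                   te(birth_year, year, bs = "ps", k = c(8, 8)) +
                   s(pid, bs = "re"),
                 family = poisson, data = pan, method = "REML")

  expect_lt(max(abs(coef(f)[2:3] - coef(g)[2:3])), 0.02)
  expect_lt(abs(f$sigma_u - mgcv::gam.vcomp(g)["s(pid)", 1L]), 0.05)

  # centred log reference surfaces agree up to basis/smoothing details
  grid <- surface_grid(f)
  s_apc <- log(reference_surface(f, grid, ndraws = 50L)$estimate)
  s_gam <- predict(g, newdata = data.frame(birth_year = grid$birth_year,
                                           year = grid$year, nilf = 0,
                                           unemp = 0, pid = pan$pid[1L]),
                   type = "link", exclude = "s(pid)",
                   newdata.guaranteed = TRUE)
  expect_gt(cor(s_apc, s_gam), 0.97)
  expect_lt(max(abs((s_apc - mean(s_apc)) - (s_gam - mean(s_gam)))), 0.3)
})
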