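# MCMC backend: full posterior sampling via JAGS with weakly-informative
# priors (Normal(0,5) on unpenalised coefficients; half-Normal(0,2) on all
# SD parameters, with tensor smoothing parameters expressed as SDs
# 1/sqrt(lambda)). Returns the same downstream interface as the Laplace
# backend, with `draws` holding the posterior sample.
fit_mcmc <- function(des, sigma_u, sigma_v, control, verbose) {
  if (!requireNamespace("rjags", quietly = TRUE)) {
    stop("backend = \"mcmc\" requires the 'rjags' package", call. = FALSE)
  }
  # block samplers for the GLM structure improve mixing substantially
  try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  y <- des$y; n <- length(y)
  pf <- des$pf; pr <- des$pr; nv <- des$nv
  use_u <- is.null(sigma_u) || sigma_u > 0
  K <- if (use_u) des$K else 0L

  lines <- c("model {",
             "  for (r in 1:n) {",
             "    y[r] ~ dpois(mu[r])",
             paste0("    log(mu[r]) <- inprod(Xf[r,], bf)",
                    if (pr) " + inprod(Xr[r,], theta)",
                    if (nv) " + v[iv[r]]",
                    if (K) " + u[iu[r]]"),
             "  }",
             "  for (j in 1:pf) { bf[j] ~ dnorm(0, 0.04) }")
  dat <- list(y = y, n = n, Xf = des$Xf, pf = pf)
  monitor <- c("bf")
  if (pr) {
    lines <- c(lines,
               "  theta ~ dmnorm(zero_r, Omega)",
               "  Omega <- lam1 * A1 + lam2 * A2",
               "  sd1 ~ dnorm(0, 0.25) T(0.01,)",
               "  sd2 ~ dnorm(0, 0.25) T(0.01,)",
               "  lam1 <- 1 / (sd1 * sd1)",
               "  lam2 <- 1 / (sd2 * sd2)")
    dat <- c(dat, list(Xr = des$Xr, zero_r = rep(0, pr),
                       A1 = des$A1, A2 = des$A2))
    monitor <- c(monitor, "theta", "lam1", "lam2")
  }
  if (nv) {
    lines <- c(lines, "  for (c in 1:nv) { v[c] ~ dnorm(0, tau_v) }")
    if (is.null(sigma_v)) {
      lines <- c(lines,
                 "  sigma_v ~ dnorm(0, 0.25) T(0.001,)",
                 "  tau_v <- 1 / (sigma_v * sigma_v)")
      monitor <- c(monitor, "sigma_v")
    } else {
      dat <- c(dat, list(tau_v = 1 / sigma_v^2))
    }
    dat <- c(dat, list(iv = des$iv, nv = nv))
    monitor <- c(monitor, "v")
  }
  if (K) {
    lines <- c(lines, "  for (i in 1:K) { u[i] ~ dnorm(0, tau_u) }")
    if (is.null(sigma_u)) {
      lines <- c(lines,
                 "  sigma_u ~ dnorm(0, 0.25) T(0.001,)",
                 "  tau_u <- 1 / (sigma_u * sigma_u)")
      monitor <- c(monitor, "sigma_u")
    } else {
      dat <- c(dat, list(tau_u = 1 / sigma_u^2))
    }
    dat <- c(dat, list(iu = des$iu, K = K))
    monitor <- c(monitor, "u")
  }
  lines <- c(lines, "}")

  inits <- lapply(seq_len(control$mcmc_chains), function(ch) {
    ii <- list(.RNG.name = "base::Mersenne-Twister",
               .RNG.seed = control$seed + ch,
               bf = c(log(mean(y) + 1e-3), rep(0, pf - 1L)))
    if (pr) { ii$sd1 <- 1; ii$sd2 <- 1; ii$theta <- rep(0, pr) }
    if (nv) { ii$v <- rep(0, nv); if (is.null(sigma_v)) ii$sigma_v <- 0.3 }
    if (K) { ii$u <- rep(0, K); if (is.null(sigma_u)) ii$sigma_u <- 0.5 }
    ii
  })
  jm <- rjags::jags.model(textConnection(paste(lines, collapse = "\n")),
                          data = dat, inits = inits,
                          n.chains = control$mcmc_chains,
                          n.adapt = control$mcmc_burnin,
                          quiet = !verbose)
  stats::update(jm, control$mcmc_burnin, progress.bar = "none")
  sam <- rjags::coda.samples(jm, monitor, n.iter = control$mcmc_iter,
                             thin = control$mcmc_thin,
                             progress.bar = "none")

  draws <- do.call(rbind, lapply(sam, as.matrix))
  cn <- colnames(draws)
  get_block <- function(stub, len) {
    if (len == 1L && stub %in% cn) return(draws[, stub, drop = FALSE])
    draws[, paste0(stub, "[", seq_len(len), "]"), drop = FALSE]
  }
  bf_d <- get_block("bf", pf)
  theta_d <- if (pr) get_block("theta", pr) else NULL
  v_d <- if (nv) get_block("v", nv) else NULL
  u_d <- if (K) get_block("u", K) else NULL
  sig_u_d <- if (K) {
    if (is.null(sigma_u)) draws[, "sigma_u"] else rep(sigma_u, nrow(draws))
  } else rep(0, nrow(draws))
  sig_v_d <- if (nv) {
    if (is.null(sigma_v)) draws[, "sigma_v"] else rep(sigma_v, nrow(draws))
  } else NULL
  lam_d <- if (pr) cbind(draws[, "lam1"], draws[, "lam2"]) else NULL

  pv_d <- cbind(bf_d, theta_d, v_d)
  b_pv <- colMeans(pv_d)
  u <- if (K) colMeans(u_d) else numeric()
  names(b_pv) <- c(des$fixed_names,
                   if (pr) paste0("surf", seq_len(pr)),
                   if (nv) paste0("v:", des$cell_levels))
  if (K) names(u) <- des$person_levels

  # split-chain convergence diagnostic on the headline scalars
  rhat <- NA_real_
  scalars <- intersect(c(paste0("bf[", seq_len(min(pf, 4L)), "]"),
                         "sigma_u", "sigma_v", "lam1", "lam2"), cn)
  if (control$mcmc_chains > 1L && length(scalars)) {
    gd <- tryCatch(
      coda::gelman.diag(sam[, scalars, drop = FALSE],
                        autoburnin = FALSE, multivariate = FALSE),
      error = function(e) NULL)
    if (!is.null(gd)) rhat <- max(gd$psrf[, 1L], na.rm = TRUE)
  }

  p <- pf + pr
  eta <- drop(des$Xf %*% b_pv[seq_len(pf)])
  if (pr) eta <- eta + drop(des$Xr %*% b_pv[pf + seq_len(pr)])
  if (nv) eta <- eta + b_pv[p + seq_len(nv)][des$iv]
  if (K) eta <- eta + u[des$iu]

  list(
    coefficients = b_pv[seq_len(pf)],
    b_pv = b_pv, u = u,
    sigma_u = if (K) mean(sig_u_d) else 0,
    sigma_v = if (nv) mean(sig_v_d) else NULL,
    lambda = if (pr) colMeans(lam_d) else NULL,
    fitted = exp(eta), linear_predictor = eta,
    loglik_conditional = sum(stats::dpois(y, exp(eta), log = TRUE)),
    criterion = NA_real_,
    edf = NA_real_,
    draws = list(pv = pv_d, u = u_d, sigma_u = sig_u_d, sigma_v = sig_v_d,
                 lambda = lam_d),
    r_idx = if (pr) pf + seq_len(pr) else integer(),
    v_idx = if (nv) p + seq_len(nv) else integer(),
    rhat = rhat,
    converged = is.na(rhat) || rhat < 1.01,
    outer_iterations = control$mcmc_iter
  )
}
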