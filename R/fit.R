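#' Control parameters for model fitting
#'
#' @param tol Outer convergence tolerance: relative change in the
#'   Laplace-approximate marginal likelihood between smoothing-parameter
#'   updates.
#' @param maxit Maximum outer (smoothing/variance update) iterations.
#' @param inner_tol Relative convergence tolerance of the penalised IRLS
#'   inner loop.
#' @param inner_maxit Maximum inner Newton iterations.
#' @param ndraws Draws from the uncertainty representation used for
#'   pointwise intervals.
#' @param refine_alpha Refine the intercept of Laplace fits by maximising
#'   the exact (adaptive Gauss-Hermite) marginal likelihood in the
#'   intercept direction; removes the small upward intercept bias of
#'   mode-based Laplace estimation. Default `TRUE`.
#' @param mcmc_iter,mcmc_burnin,mcmc_chains,mcmc_thin MCMC backend sampler
#'   settings (post-burn-in iterations per chain, adaptation/burn-in,
#'   chains, thinning).
#' @param seed Seed for any stochastic step (MCMC, interval draws).
#' @return List of class `apc_control`.
#' @export
apc_control <- function(tol = 1e-8, maxit = 200L,
                        inner_tol = 1e-11, inner_maxit = 100L,
                        ndraws = 4000L, refine_alpha = TRUE,
                        mcmc_iter = 2000L, mcmc_burnin = 1000L,
                        mcmc_chains = 2L, mcmc_thin = 1L,
                        seed = 1L) {
  out <- list(tol = tol, maxit = as.integer(maxit),
              inner_tol = inner_tol, inner_maxit = as.integer(inner_maxit),
              ndraws = as.integer(ndraws),
              refine_alpha = isTRUE(refine_alpha),
              mcmc_iter = as.integer(mcmc_iter),
              mcmc_burnin = as.integer(mcmc_burnin),
              mcmc_chains = as.integer(mcmc_chains),
              mcmc_thin = as.integer(mcmc_thin),
              seed = as.integer(seed))
  class(out) <- "apc_control"
  out
}

#' Fit the hierarchical Poisson age-period-cohort model
#'
#' Fits, to a person-year panel of visit counts, the model
#' \deqn{y_{it} \sim \mathrm{Poisson}(\mu_{it}), \quad
#'   \log \mu_{it} = \alpha + u_i + s(C_i, t) +
#'   \beta_1\,\mathrm{nilf}_{it} + \beta_2\,\mathrm{unemployed}_{it}
#'   (+ \beta_3\,\mathrm{perinatal}_{it}), \quad u_i \sim N(0, \sigma_u)}
#' where s(C, t) is a tensor-product P-spline surface over birth cohort and
#' calendar period with anisotropic smoothing. Model variants replace the
#' smooth surface by independent domain intercepts v_{C,t} ~ N(0, sigma_v)
#' (`"domain_re"`, partial pooling), by nothing (`"pooled"`, complete
#' pooling), or include both (`"smooth_plus_domain_re"`).
#'
#' The default `"laplace"` backend maximises the Laplace-approximate
#' (REML-type) marginal likelihood: a penalised IRLS Newton inner loop over
#' all coefficients, with the person-intercept block eliminated through its
#' diagonal Hessian, nested inside Fellner-Schall updates of the smoothing
#' parameters and random-effect standard deviations. The `"mcmc"` backend
#' samples the full posterior with weakly-informative priors via JAGS
#' (requires the `rjags` package) and is retained for fidelity checks; both
#' return the same downstream interface.
#'
#' @param panel Person-year panel from [build_panel()] or
#'   [simulate_panel()].
#' @param variant Model variant, one of `"smooth"`, `"domain_re"`,
#'   `"pooled"`, `"smooth_plus_domain_re"`.
#' @param covariates Subset of `c("nilf", "unemployed", "perinatal")`.
#'   Default: labour-force dummies always, plus `perinatal` when the panel
#'   contains flagged rows.
#' @param k Length-2 marginal basis dimensions (cohort, period) for the
#'   smooth variants.
#' @param degree,penalty_order Spline degree and difference-penalty order.
#' @param backend `"laplace"` (default) or `"mcmc"`.
#' @param sigma_u Person-frailty SD: `NULL` to estimate, a number to fix
#'   (0 removes the person intercept entirely).
#' @param sigma_v Domain-intercept SD for the `domain_re` variants: `NULL`
#'   to estimate or a positive number to fix.
#' @param lambda Optional fixed length-2 vector of tensor smoothing
#'   parameters (cohort, period); `NULL` to estimate.
#' @param control An [apc_control()] list.
#' @param verbose Print outer-iteration progress.
#'
#' @return Object of class `apc_fit`; see [summary.apc_fit()],
#'   [reference_surface()], [log_pointwise_density()].
#' @references Wood, S. N. and Fasiolo, M. (2017) A generalized
#'   Fellner-Schall method for smoothing parameter optimization with
#'   application to Tweedie location, scale and shape models. Biometrics
#'   73, 1071-1081.
#' @export
apc_fit <- function(panel,
                    variant = c("smooth", "domain_re", "pooled",
                                "smooth_plus_domain_re"),
                    covariates = NULL,
                    k = c(8L, 8L), degree = 3L, penalty_order = 2L,
                    backend = c("laplace", "mcmc"),
                    sigma_u = NULL, sigma_v = NULL, lambda = NULL,
                    control = apc_control(), verbose = FALSE) {
  variant <- match.arg(variant)
  backend <- match.arg(backend)
  panel <- validate_panel(panel)
  if (all(panel$count == 0)) {
    stop("all counts are zero: degenerate data, nothing to fit",
         call. = FALSE)
  }
  if (is.null(covariates)) {
    covariates <- c("nilf", "unemployed")
    if (any(panel$perinatal)) covariates <- c(covariates, "perinatal")
  }
  if (length(covariates)) {
    covariates <- match.arg(covariates, c("nilf", "unemployed", "perinatal"),
                            several.ok = TRUE)
  }
  if ("perinatal" %in% covariates && !any(panel$perinatal)) {
    stop("'perinatal' covariate requested but no flagged rows in panel",
         call. = FALSE)
  }

  des <- build_design(panel, variant, covariates, k, degree, penalty_order)

  fit <- if (backend == "laplace") {
    fit_laplace(des, sigma_u = sigma_u, sigma_v = sigma_v, lambda = lambda,
                control = control, verbose = verbose)
  } else {
    fit_mcmc(des, sigma_u = sigma_u, sigma_v = sigma_v,
             control = control, verbose = verbose)
  }

  fit$call <- match.call()
  fit$variant <- variant
  fit$covariates <- covariates
  fit$backend <- backend
  fit$panel <- panel
  fit$basis <- des$basis
  fit$design <- des[c("person_levels", "cell_levels", "cell_key",
                      "fixed_names", "pf", "pr", "nv", "K")]
  fit$control <- control
  class(fit) <- "apc_fit"
  fit
}

# -- design assembly ----------------------------------------------------------

build_design <- function(panel, variant, covariates, k, degree,
                         penalty_order) {
  y <- as.integer(panel$count)
  n <- length(y)

  Xf <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  if ("nilf" %in% covariates) {
    Xf <- cbind(Xf, nilf = as.numeric(panel$employment_status == "nilf"))
  }
  if ("unemployed" %in% covariates) {
    Xf <- cbind(Xf,
                unemployed = as.numeric(panel$employment_status == "unemployed"))
  }
  if ("perinatal" %in% covariates) {
    Xf <- cbind(Xf, perinatal = as.numeric(panel$perinatal))
  }

  basis <- NULL; Xr <- NULL; A1 <- NULL; A2 <- NULL
  if (variant %in% c("smooth", "smooth_plus_domain_re")) {
    basis <- tensor_basis(panel, k[1L], k[max(1L, length(k))], degree,
                          penalty_order)
    if (ncol(basis$Xn)) {
      Xn <- basis$Xn
      colnames(Xn) <- paste0("surf_lin", seq_len(ncol(Xn)))
      Xf <- cbind(Xf, Xn)
    }
    Xr <- basis$Xr
    A1 <- basis$A1; A2 <- basis$A2
  }

  person_levels <- unique(panel$person_id)
  iu <- match(panel$person_id, person_levels)

  cell_levels <- NULL; iv <- NULL; cell_key <- NULL
  if (variant %in% c("domain_re", "smooth_plus_domain_re")) {
    cell_key <- paste(panel$birth_year, panel$year, sep = ":")
    cell_levels <- unique(cell_key)
    iv <- match(cell_key, cell_levels)
  }

  list(y = y, Xf = Xf, Xr = Xr, A1 = A1, A2 = A2,
       iu = iu, iv = iv,
       person_levels = person_levels, cell_levels = cell_levels,
       cell_key = cell_key, basis = basis,
       fixed_names = colnames(Xf),
       pf = ncol(Xf), pr = if (is.null(Xr)) 0L else ncol(Xr),
       nv = if (is.null(cell_levels)) 0L else length(cell_levels),
       K = length(person_levels))
}

# -- Laplace backend ----------------------------------------------------------

# Layout of the "pv" (dense + domain) coefficient block:
#   [1..pf]            fixed effects incl. unpenalised surface columns
#   [pf+1..pf+pr]      penalised tensor coefficients
#   [pf+pr+1..+nv]     domain random intercepts v
# The person intercepts u form a separate block eliminated via its diagonal
# Hessian; see the Schur-complement identities in the helpers below.
fit_laplace <- function(des, sigma_u, sigma_v, lambda, control, verbose) {
  y <- des$y; n <- length(y)
  pf <- des$pf; pr <- des$pr; nv <- des$nv

  use_u <- is.null(sigma_u) || sigma_u > 0
  K <- if (use_u) des$K else 0L
  iu <- if (use_u) des$iu else NULL
  iv <- des$iv

  Xd <- if (pr) cbind(des$Xf, des$Xr) else des$Xf
  p <- pf + pr
  r_idx <- if (pr) pf + seq_len(pr) else integer()
  v_idx <- if (nv) p + seq_len(nv) else integer()

  # one sparse design over [covariates | raw tensor | domain cells |
  # persons]; every Hessian block falls out of a single sparse
  # cross-product. Tensor columns enter RAW (sparse B-splines); the
  # constraint / null-space transform Ttens is applied at the Hessian
  # level inside pirls, so the coefficient vector stays in the
  # constrained parameterisation.
  nn <- if (pr) ncol(des$basis$Un) else 0L   # unpenalised surface columns
  pcov <- pf - nn                            # covariate block size
  Ttens <- if (pr) des$basis$Ttens else NULL
  Xcov <- des$Xf[, seq_len(pcov), drop = FALSE]
  Zs <- methods::as(Matrix::Matrix(Xcov, sparse = TRUE), "CsparseMatrix")
  if (pr) {
    Braw <- des$basis$B_raw
    Braw[abs(Braw) < 1e-300] <- 0
    Zs <- Matrix::cbind2(Zs, methods::as(Matrix::Matrix(Braw, sparse = TRUE),
                                         "CsparseMatrix"))
  }
  if (nv) {
    Zs <- Matrix::cbind2(Zs, Matrix::sparseMatrix(i = seq_len(n), j = iv,
                                                  x = 1, dims = c(n, nv)))
  }

  # hyperparameters on the log-precision scale
  free <- c(lam1 = pr > 0 && is.null(lambda),
            lam2 = pr > 0 && is.null(lambda),
            lam_u = K > 0 && is.null(sigma_u),
            lam_v = nv > 0 && is.null(sigma_v))
  lam <- c(lam1 = if (pr) (if (is.null(lambda)) 1 else lambda[1L]) else NA,
           lam2 = if (pr) (if (is.null(lambda)) 1 else lambda[2L]) else NA,
           lam_u = if (K) (if (is.null(sigma_u)) 1 / 0.25 else 1 / sigma_u^2)
                   else NA,
           lam_v = if (nv) (if (is.null(sigma_v)) 1 / 0.25 else 1 / sigma_v^2)
                   else NA)
  lam_lo <- 1e-7; lam_hi <- 1e10

  b_pv <- numeric(p + nv)
  b_pv[1L] <- log(mean(y) + 1e-3)
  u <- numeric(K)

  state <- NULL
  crit_old <- -Inf
  converged <- FALSE
  outer_used <- 0L
  # momentum for the multiplicative updates: repeated same-direction steps
  # (e.g. a variance collapsing to zero) get geometrically growing strides
  mom <- rep(1, length(lam)); names(mom) <- names(lam)
  prev_dir <- rep(0, length(lam)); names(prev_dir) <- names(lam)

  for (outer in seq_len(control$maxit)) {
    outer_used <- outer
    state <- pirls(y, Zs, des$A1, des$A2, p, nv, K, iu, pcov, Ttens,
                   r_idx, v_idx, lam, b_pv, u, control)
    b_pv <- state$b_pv; u <- state$u

    crit <- laplace_criterion(state, lam, des$A1, des$A2, pf, pr, K, nv,
                              r_idx, v_idx)
    if (verbose) {
      message(sprintf("outer %3d  criterion %.6f  lambda %s", outer, crit,
                      paste(signif(lam[!is.na(lam)], 4), collapse = " ")))
    }
    if (!any(free)) { converged <- state$converged; break }

    upd <- fellner_schall(state, lam, des$A1, des$A2, r_idx, v_idx,
                          free, lam_lo, lam_hi)
    step <- ifelse(free, log(upd / lam), 0)
    dir <- sign(step)
    same <- dir != 0 & dir == prev_dir & abs(step) > 1e-4
    mom <- ifelse(same, pmin(mom * 2, 16), 1)
    prev_dir <- dir
    upd <- pmin(pmax(lam * exp(mom * step), lam_lo), lam_hi)
    moved <- max(abs(log(upd[free] / lam[free])))

    if (abs(crit - crit_old) < control$tol * (abs(crit) + 1) ||
        moved < 1e-6) {
      converged <- state$converged
      break
    }
    lam <- upd
    crit_old <- crit
  }
  crit <- laplace_criterion(state, lam, des$A1, des$A2, pf, pr, K, nv,
                            r_idx, v_idx)

  # Mode-based Laplace slightly overstates the intercept because posterior
  # modes of u understate E[exp(u)]; refine alpha by maximising the exact
  # (adaptive Gauss-Hermite) marginal likelihood in the intercept direction,
  # holding the other coefficients, u modes and variance parameters fixed.
  delta <- 0
  if (K && control$refine_alpha) {
    eta_ref <- drop(Xd %*% b_pv[seq_len(p)])
    if (nv) eta_ref <- eta_ref + b_pv[v_idx][iv]
    delta <- refine_alpha_agq(y, eta_ref, iu, u, state$d,
                              1 / sqrt(lam[["lam_u"]]))
    b_pv[1L] <- b_pv[1L] + delta
  }

  names(b_pv) <- c(des$fixed_names,
                   if (pr) paste0("surf", seq_len(pr)),
                   if (nv) paste0("v:", des$cell_levels))
  if (K) names(u) <- des$person_levels

  eta <- state$eta + delta
  list(
    coefficients = b_pv[seq_len(pf)],
    b_pv = b_pv, u = u,
    sigma_u = if (K) 1 / sqrt(lam[["lam_u"]]) else 0,
    sigma_v = if (nv) 1 / sqrt(lam[["lam_v"]]) else NULL,
    lambda = if (pr) unname(lam[c("lam1", "lam2")]) else NULL,
    fitted = exp(eta), linear_predictor = eta,
    loglik_conditional = sum(stats::dpois(y, exp(eta), log = TRUE)),
    criterion = crit,
    edf = state$edf,
    R = state$R, J = state$J, d_u = state$d,
    r_idx = r_idx, v_idx = v_idx,
    converged = converged, outer_iterations = outer_used
  )
}

# Penalised IRLS: Newton on the joint penalised Poisson log-likelihood.
# The design is sparse in the RAW tensor parameterisation; gradients and
# Hessian blocks are mapped into the constrained parameterisation through
# Ttens. The person block never enters the sparse cross-product: its
# Hessian is diagonal and is eliminated analytically.
pirls <- function(y, Zs, A1, A2, p, nv, K, iu, pcov, Ttens, r_idx, v_idx,
                  lam, b_pv, u, control) {
  n <- length(y)
  Sr <- if (length(r_idx)) lam[["lam1"]] * A1 + lam[["lam2"]] * A2 else NULL
  pv <- p + nv
  ntens <- if (is.null(Ttens)) 0L else nrow(Ttens)   # raw tensor columns
  nt <- if (is.null(Ttens)) 0L else ncol(Ttens)      # constrained columns
  nraw_pv <- pcov + ntens + nv
  # index maps raw <-> constrained within the pv block
  cov_idx <- seq_len(pcov)
  tt_idx <- if (nt) pcov + seq_len(nt) else integer()      # constrained
  tr_idx <- if (ntens) pcov + seq_len(ntens) else integer() # raw
  vr_idx <- if (nv) pcov + ntens + seq_len(nv) else integer()

  to_raw <- function(b_pv) {
    raw <- numeric(nraw_pv)
    raw[cov_idx] <- b_pv[cov_idx]
    if (nt) raw[tr_idx] <- drop(Ttens %*% b_pv[tt_idx])
    if (nv) raw[vr_idx] <- b_pv[v_idx]
    raw
  }
  penll <- function(b_pv, u, eta) {
    ll <- sum(y * eta - exp(eta))
    if (length(r_idx)) {
      br <- b_pv[r_idx]; ll <- ll - 0.5 * drop(crossprod(br, Sr %*% br))
    }
    if (nv) ll <- ll - 0.5 * lam[["lam_v"]] * sum(b_pv[v_idx]^2)
    if (K) ll <- ll - 0.5 * lam[["lam_u"]] * sum(u^2)
    ll
  }
  eta_of <- function(b_pv, u) {
    eta <- as.numeric(Zs %*% to_raw(b_pv))
    if (K) eta <- eta + u[iu]
    pmin(eta, 30)
  }

  hessian_blocks <- function(w) {
    Hs <- Matrix::crossprod(Matrix::Diagonal(x = sqrt(w)) %*% Zs)
    Hraw <- as.matrix(Hs)
    # transform the raw tensor rows/columns into the constrained space
    Hd <- matrix(0, pv, pv)
    oc <- c(cov_idx, v_idx); or <- c(cov_idx, vr_idx)
    Hd[oc, oc] <- Hraw[or, or]
    if (nt) {
      Hd[tt_idx, tt_idx] <- crossprod(Ttens, Hraw[tr_idx, tr_idx] %*% Ttens)
      cross <- Hraw[or, tr_idx, drop = FALSE] %*% Ttens
      Hd[oc, tt_idx] <- cross
      Hd[tt_idx, oc] <- t(cross)
    }
    if (length(r_idx)) Hd[r_idx, r_idx] <- Hd[r_idx, r_idx] + Sr
    if (nv) Hd[cbind(v_idx, v_idx)] <- Hd[cbind(v_idx, v_idx)] + lam[["lam_v"]]
    if (K) {
      d <- drop(rowsum(w, iu)) + lam[["lam_u"]]
      # cross-Hessian with the person block: person-aggregated weighted rows
      Wu <- Matrix::sparseMatrix(i = seq_len(n), j = iu, x = w,
                                 dims = c(n, K))
      Jraw <- Matrix::crossprod(Zs, Wu)           # nraw_pv x K, sparse
      J <- matrix(0, pv, K)
      J[oc, ] <- as.matrix(Jraw[or, , drop = FALSE])
      if (nt) {
        J[tt_idx, ] <- crossprod(Ttens, as.matrix(Jraw[tr_idx, ,
                                                       drop = FALSE]))
      }
      Jsp <- methods::as(Matrix::Matrix(J, sparse = TRUE), "CsparseMatrix")
      Ht <- Hd - as.matrix(Matrix::tcrossprod(
        Jsp %*% Matrix::Diagonal(x = 1 / sqrt(d))))
    } else {
      d <- NULL; J <- NULL; Jsp <- NULL; Ht <- Hd
    }
    list(Ht = Ht, J = J, Jsp = Jsp, d = d)
  }

  grad_pv <- function(res, b_pv) {
    g_raw <- as.numeric(Matrix::crossprod(Zs, res))
    g <- numeric(pv)
    g[cov_idx] <- g_raw[cov_idx]
    if (nt) g[tt_idx] <- drop(crossprod(Ttens, g_raw[tr_idx]))
    if (nv) g[v_idx] <- g_raw[vr_idx] - lam[["lam_v"]] * b_pv[v_idx]
    if (length(r_idx)) g[r_idx] <- g[r_idx] - drop(Sr %*% b_pv[r_idx])
    g
  }

  eta <- eta_of(b_pv, u)
  ll <- penll(b_pv, u, eta)
  conv <- FALSE
  hb <- NULL
  last_step <- Inf

  for (it in seq_len(control$inner_maxit)) {
    w <- exp(eta)
    res <- y - w

    g_pv <- grad_pv(res, b_pv)
    g_u <- if (K) drop(rowsum(res, iu)) - lam[["lam_u"]] * u else NULL

    hb <- hessian_blocks(w)
    g_t <- if (K) g_pv - as.numeric(hb$Jsp %*% (g_u / hb$d)) else g_pv

    R <- tryCatch(chol(hb$Ht), error = function(e) {
      chol(hb$Ht + diag(1e-8 * max(diag(hb$Ht)), nrow(hb$Ht)))
    })
    delta_pv <- backsolve(R, forwardsolve(t(R), g_t))
    delta_u <- if (K) {
      (g_u - as.numeric(Matrix::crossprod(hb$Jsp, delta_pv))) / hb$d
    } else NULL

    # step halving on penalised log-likelihood decrease
    step <- 1
    repeat {
      b_new <- b_pv + step * delta_pv
      u_new <- if (K) u + step * delta_u else u
      eta_new <- eta_of(b_new, u_new)
      ll_new <- penll(b_new, u_new, eta_new)
      if (is.finite(ll_new) && (ll_new >= ll - 1e-12)) break
      step <- step / 2
      if (step < 1e-10) { ll_new <- ll; b_new <- b_pv; u_new <- u
        eta_new <- eta; break }
    }
    last_step <- step * max(abs(delta_pv),
                            if (K) max(abs(delta_u)) else 0)
    done <- abs(ll_new - ll) < control$inner_tol * (abs(ll) + 1)
    b_pv <- b_new; u <- u_new; eta <- eta_new; ll <- ll_new
    if (done) { conv <- TRUE; break }
  }

  # factorisation at the accepted coefficients; when the final Newton step
  # was negligible the blocks from the last iteration already apply
  if (last_step > 1e-7) {
    hb <- hessian_blocks(exp(eta))
  }
  R <- tryCatch(chol(sym(hb$Ht)), error = function(e) {
    chol(sym(hb$Ht) + diag(1e-8 * max(diag(hb$Ht)), nrow(hb$Ht)))
  })
  J <- hb$J; d <- hb$d

  # traces for the Fellner-Schall updates and effective df
  Hinv <- chol2inv(R)                      # [H^{-1}] over the pv block
  tr_uu <- if (K) {
    Q <- as.matrix(Hinv %*% hb$Jsp)
    sum(1 / d) + sum(colSums(J * Q) / d^2)
  } else NULL

  pen_ll <- penll(b_pv, u, eta) - sum(lfactorial(y))
  edf <- edf_from(Hinv, tr_uu, lam, A1, A2, r_idx, v_idx, K,
                  p_total = pv + K)

  list(b_pv = b_pv, u = u, eta = eta, pen_ll = pen_ll,
       R = R, Hinv = Hinv, J = J, d = d,
       tr_uu = tr_uu, converged = conv, edf = edf)
}

# Exact marginal log-likelihood in the intercept direction by per-person
# adaptive Gauss-Hermite quadrature (abscissae centred at the posterior
# modes with the mode curvature as scale). Returns the maximising shift.
refine_alpha_agq <- function(y, eta_ref, iu, u, d, sigma_u, ngh = 12L) {
  gh <- gauss_hermite(ngh)
  K <- length(u)
  si <- 1 / sqrt(d)
  U <- outer(sqrt(2) * si, gh$nodes) + u         # K x ngh abscissae
  const <- matrix(rep(gh$logw + gh$nodes^2, each = K), K, ngh) +
    log(sqrt(2) * si) + stats::dnorm(U, 0, sigma_u, log = TRUE)
  marg <- function(delta) {
    lw <- const
    for (k in seq_len(ngh)) {
      lw[, k] <- lw[, k] + drop(rowsum(
        stats::dpois(y, exp(eta_ref + delta + U[iu, k]), log = TRUE),
        iu, reorder = FALSE))[order_map(iu)]
    }
    mx <- apply(lw, 1L, max)
    sum(mx + log(rowSums(exp(lw - mx))))
  }
  stats::optimize(marg, c(-0.3, 0.3), maximum = TRUE, tol = 1e-5)$maximum
}

order_map <- function(idx) {
  # rowsum(reorder = FALSE) groups in first-appearance order; map back to
  # level order 1..max(idx)
  first <- !duplicated(idx)
  match(seq_len(max(idx)), idx[first])
}

edf_from <- function(Hinv, tr_uu, lam, A1, A2, r_idx, v_idx, K, p_total) {
  tr_pen <- 0
  if (length(r_idx)) {
    Sr <- lam[["lam1"]] * A1 + lam[["lam2"]] * A2
    tr_pen <- tr_pen + sum(Hinv[r_idx, r_idx] * Sr)
  }
  if (length(v_idx)) {
    tr_pen <- tr_pen + lam[["lam_v"]] * sum(diag(Hinv)[v_idx])
  }
  if (K) tr_pen <- tr_pen + lam[["lam_u"]] * tr_uu
  p_total - tr_pen
}

# Laplace-approximate marginal likelihood (REML type: fixed effects
# integrated with a flat prior).
laplace_criterion <- function(state, lam, A1, A2, pf, pr, K, nv,
                              r_idx, v_idx) {
  logdet_H <- 2 * sum(log(diag(state$R))) +
    if (K) sum(log(state$d)) else 0
  logdet_L <- 0
  if (pr) {
    Sr <- lam[["lam1"]] * A1 + lam[["lam2"]] * A2
    logdet_L <- logdet_L + 2 * sum(log(diag(chol(Sr))))
  }
  if (K) logdet_L <- logdet_L + K * log(lam[["lam_u"]])
  if (nv) logdet_L <- logdet_L + nv * log(lam[["lam_v"]])
  state$pen_ll + 0.5 * logdet_L - 0.5 * logdet_H + 0.5 * pf * log(2 * pi)
}

# One extended Fellner-Schall update of the free log-smoothing parameters.
fellner_schall <- function(state, lam, A1, A2, r_idx, v_idx, free,
                           lam_lo, lam_hi) {
  Hinv <- state$Hinv
  b_pv <- state$b_pv
  new <- lam
  step_clip <- function(ratio) min(max(ratio, 1e-3), 1e3)

  if (free[["lam1"]] || free[["lam2"]]) {
    Sr <- lam[["lam1"]] * A1 + lam[["lam2"]] * A2
    Sinv <- chol2inv(chol(Sr))
    br <- b_pv[r_idx]
    Hrr <- Hinv[r_idx, r_idx]
    for (j in 1:2) {
      key <- c("lam1", "lam2")[j]
      if (!free[[key]]) next
      Aj <- if (j == 1L) A1 else A2
      num <- sum(Sinv * Aj) - sum(Hrr * Aj)
      den <- drop(crossprod(br, Aj %*% br))
      ratio <- if (den > 1e-12 && num > 0) num / den else lam_hi / lam[[key]]
      new[[key]] <- min(max(lam[[key]] * step_clip(ratio), lam_lo), lam_hi)
    }
  }
  if (free[["lam_u"]]) {
    K <- length(state$u)
    num <- K / lam[["lam_u"]] - state$tr_uu
    den <- sum(state$u^2)
    ratio <- if (den > 1e-12 && num > 0) num / den else lam_hi / lam[["lam_u"]]
    new[["lam_u"]] <- min(max(lam[["lam_u"]] * step_clip(ratio), lam_lo),
                          lam_hi)
  }
  if (free[["lam_v"]]) {
    nv <- length(v_idx)
    vv <- b_pv[v_idx]
    num <- nv / lam[["lam_v"]] - sum(diag(Hinv)[v_idx])
    den <- sum(vv^2)
    ratio <- if (den > 1e-12 && num > 0) num / den else lam_hi / lam[["lam_v"]]
    new[["lam_v"]] <- min(max(lam[["lam_v"]] * step_clip(ratio), lam_lo),
                          lam_hi)
  }
  new
}
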