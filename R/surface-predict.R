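#' Default prediction grid of a fitted model
#'
#' One-year steps over the observed cohort x period rectangle, clipped to
#' the observed age range (ages outside what the data contain are never
#' predicted).
#'
#' @param fit An `apc_fit` object.
#' @return Data frame with columns `birth_year`, `year`, `age`.
#' @export
surface_grid <- function(fit) {
  stopifnot(inherits(fit, "apc_fit"))
  pn <- fit$panel
  g <- expand.grid(birth_year = min(pn$birth_year):max(pn$birth_year),
                   year = min(pn$year):max(pn$year))
  g$age <- g$year - g$birth_year
  g <- g[g$age >= min(pn$age) & g$age <= max(pn$age), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Reference-person prediction surface
#'
#' Expected annual visit counts over the cohort x period grid for the
#' reference person: employed, no peri-natal services, random intercept
#' u = 0 (the "median person"). Estimands:
#' \describe{
#'   \item{median_person}{exp(alpha + s(C, t)); the rate of the reference
#'     person with median (zero) frailty.}
#'   \item{population_mean}{the median-person rate times E exp(u) =
#'     exp(sigma_u^2 / 2), the mean over the frailty distribution.}
#'   \item{proportion_le_k}{probability that an annual count is at most
#'     `k_le`, integrating the Poisson CDF over u ~ N(0, sigma_u).}
#' }
#' Point estimates are plug-in at the estimated coefficients; `lower` and
#' `upper` are pointwise equal-tailed 95% bounds over draws from the fit's
#' uncertainty representation (Gaussian approximation or posterior draws).
#'
#' @param fit Converged `apc_fit`.
#' @param grid Data frame with `birth_year` and `year` columns inside the
#'   fitted ranges; default [surface_grid()]. No extrapolation: values
#'   outside the fitted rectangle are an error.
#' @param estimand One of `"median_person"`, `"population_mean"`,
#'   `"proportion_le_k"`.
#' @param k_le Count threshold for `proportion_le_k` (default 2).
#' @param level Interval coverage (default 0.95).
#' @param ndraws Draws for the intervals (default from the fit's control).
#' @param allow_unconverged Predict from a non-converged fit anyway.
#'
#' @return Data frame of class `apc_surface` with columns `birth_year`,
#'   `year`, `age`, `estimate`, `lower`, `upper`.
#' @export
reference_surface <- function(fit, grid = NULL,
                              estimand = c("median_person",
                                           "population_mean",
                                           "proportion_le_k"),
                              k_le = 2L, level = 0.95, ndraws = NULL,
                              allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "apc_fit"))
  estimand <- match.arg(estimand)
  if (!fit$converged && !allow_unconverged) {
    stop("fit did not converge; pass allow_unconverged = TRUE to override",
         call. = FALSE)
  }
  if (is.null(grid)) grid <- surface_grid(fit)
  stopifnot(all(c("birth_year", "year") %in% names(grid)))
  if (is.null(grid$age)) grid$age <- grid$year - grid$birth_year
  if (is.null(ndraws)) ndraws <- fit$control$ndraws

  ed <- eta0_draws(fit, grid, ndraws)
  gh <- gauss_hermite(25L)

  transform <- function(eta, sigma_u) {
    switch(estimand,
           median_person = exp(eta),
           population_mean = exp(eta + sigma_u^2 / 2),
           proportion_le_k = {
             if (sigma_u > 0) {
               # Gauss-Hermite integral of the Poisson CDF over the frailty
               P <- stats::ppois(k_le,
                                 exp(outer(eta, sqrt(2) * sigma_u * gh$nodes,
                                           "+")))
               drop(P %*% exp(gh$logw)) / sqrt(pi)
             } else stats::ppois(k_le, exp(eta))
           })
  }

  est <- transform(ed$eta0, fit$sigma_u)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  # per-draw transform (sigma_u varies over draws under mcmc)
  vals <- vapply(seq_len(nrow(ed$draws)), function(s) {
    transform(ed$draws[s, ], ed$sigma_u_draws[s])
  }, numeric(nrow(grid)))
  lims <- apply(vals, 1L, stats::quantile, probs = qs, names = FALSE)

  out <- data.frame(birth_year = grid$birth_year, year = grid$year,
                    age = grid$age, estimate = est,
                    lower = lims[1L, ], upper = lims[2L, ])
  attr(out, "estimand") <- estimand
  if (estimand == "proportion_le_k") attr(out, "k_le") <- k_le
  class(out) <- c("apc_surface", "data.frame")
  out
}

# Linear predictor of the reference person (u = 0, reference covariates)
# on the grid: plug-in value `eta0` plus `ndraws` draws from the fit's
# uncertainty representation (rows = draws).
eta0_draws <- function(fit, grid, ndraws, seed_offset = 0L) {
  pf <- fit$design$pf; pr <- fit$design$pr; nv <- fit$design$nv
  p <- pf + pr
  n <- nrow(grid)

  # reference covariates: intercept only, all dummies zero
  Xp <- matrix(0, n, p)
  Xp[, 1L] <- 1
  if (!is.null(fit$basis)) {
    te <- tensor_eval(fit$basis, grid$birth_year, grid$year)
    nn <- ncol(te$Xn)
    if (nn) {
      first_surf <- match(paste0("surf_lin", 1L), fit$design$fixed_names)
      Xp[, first_surf + seq_len(nn) - 1L] <- te$Xn
    }
    if (pr) Xp[, pf + seq_len(pr)] <- te$Xr
  }
  iv <- if (nv) {
    match(paste(grid$birth_year, grid$year, sep = ":"),
          fit$design$cell_levels)
  } else NULL

  eta0 <- drop(Xp %*% fit$b_pv[seq_len(p)])
  if (nv) {
    vhat <- fit$b_pv[fit$v_idx]
    eta0 <- eta0 + ifelse(is.na(iv), 0, vhat[ifelse(is.na(iv), 1L, iv)])
  }

  if (fit$backend == "mcmc") {
    pv_d <- fit$draws$pv
    take <- if (nrow(pv_d) > ndraws) {
      round(seq(1L, nrow(pv_d), length.out = ndraws))
    } else seq_len(nrow(pv_d))
    draws <- tcrossprod(pv_d[take, seq_len(p), drop = FALSE], Xp)
    if (nv) {
      vd <- pv_d[take, p + seq_len(nv), drop = FALSE]
      seen <- which(!is.na(iv))
      if (length(seen)) draws[, seen] <- draws[, seen] + vd[, iv[seen]]
    }
    sig_d <- fit$draws$sigma_u[take]
  } else {
    # joint Gaussian draws over the dense+domain block
    z <- with_seed(fit$control$seed + seed_offset, {
      matrix(stats::rnorm(ndraws * nrow(fit$R)), nrow(fit$R), ndraws)
    })
    bd <- fit$b_pv + backsolve(fit$R, z)        # (p+nv) x ndraws
    draws <- crossprod(bd[seq_len(p), , drop = FALSE], t(Xp))  # ndraws x n
    if (nv) {
      vd <- t(bd[p + seq_len(nv), , drop = FALSE])
      seen <- which(!is.na(iv))
      if (length(seen)) draws[, seen] <- draws[, seen] + vd[, iv[seen]]
    }
    sig_d <- rep(fit$sigma_u, nrow(draws))
  }
  list(eta0 = eta0, draws = draws, sigma_u_draws = sig_d, Xp = Xp, iv = iv)
}

#' Covariate relative rates with 95% intervals
#'
#' Multiplicative effects exp(beta) of the labour-force and peri-natal
#' adjustment covariates on the visit rate, with equal-tailed 95%
#' intervals from the fit's uncertainty representation.
#'
#' @param fit An `apc_fit` object.
#' @param level Interval coverage.
#' @return Data frame with columns `covariate`, `rr`, `lower`, `upper`.
#' @export
covariate_relative_rates <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "apc_fit"))
  idx <- match(fit$covariates, fit$design$fixed_names)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (fit$backend == "mcmc") {
    dr <- fit$draws$pv[, idx, drop = FALSE]
    qs <- apply(dr, 2L, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2))
    data.frame(covariate = fit$covariates,
               rr = exp(colMeans(dr)),
               lower = exp(qs[1L, ]), upper = exp(qs[2L, ]),
               row.names = NULL)
  } else {
    Hinv <- chol2inv(fit$R)
    se <- sqrt(diag(Hinv)[idx])
    b <- fit$b_pv[idx]
    data.frame(covariate = fit$covariates,
               rr = exp(b),
               lower = exp(b - z * se), upper = exp(b + z * se),
               row.names = NULL)
  }
}

#' Contrast two independently fitted models on a shared grid
#'
#' Pointwise difference of median-person expected counts (fit_a - fit_b),
#' e.g. reference women minus reference men, with intervals obtained by
#' independently combining the two fits' uncertainty draws (the models are
#' fitted to disjoint strata).
#'
#' @param fit_a,fit_b Converged `apc_fit` objects.
#' @param grid Shared grid; default the intersection of the two default
#'   grids.
#' @param level Interval coverage.
#' @param ndraws Draws per fit.
#' @return Data frame of class `apc_contrast` with columns `birth_year`,
#'   `year`, `age`, `difference`, `lower`, `upper`.
#' @export
contrast <- function(fit_a, fit_b, grid = NULL, level = 0.95,
                     ndraws = NULL) {
  stopifnot(inherits(fit_a, "apc_fit"), inherits(fit_b, "apc_fit"))
  if (is.null(grid)) {
    ga <- surface_grid(fit_a); gb <- surface_grid(fit_b)
    key <- intersect(paste(ga$birth_year, ga$year),
                     paste(gb$birth_year, gb$year))
    grid <- ga[paste(ga$birth_year, ga$year) %in% key, , drop = FALSE]
  }
  if (is.null(ndraws)) ndraws <- fit_a$control$ndraws
  # distinct seed offsets: the two fits' uncertainty draws must be
  # independent even when both fits carry the same control seed
  ea <- eta0_draws(fit_a, grid, ndraws, seed_offset = 0L)
  eb <- eta0_draws(fit_b, grid, ndraws, seed_offset = 104729L)
  nd <- min(nrow(ea$draws), nrow(eb$draws))
  dd <- exp(ea$draws[seq_len(nd), , drop = FALSE]) -
    exp(eb$draws[seq_len(nd), , drop = FALSE])
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  lims <- apply(dd, 2L, stats::quantile, probs = qs, names = FALSE)
  out <- data.frame(birth_year = grid$birth_year, year = grid$year,
                    age = grid$year - grid$birth_year,
                    difference = exp(ea$eta0) - exp(eb$eta0),
                    lower = lims[1L, ], upper = lims[2L, ])
  class(out) <- c("apc_contrast", "data.frame")
  out
}

#' Export a prediction or contrast surface to CSV
#'
#' Writes the surface with full double precision (17 significant digits),
#' so reading the file back reproduces the values exactly. Optionally
#' restricts to selected birth cohorts for line-plot extraction.
#'
#' @param surface An `apc_surface` or `apc_contrast` data frame.
#' @param path Output CSV path.
#' @param cohorts Optional vector of birth years to keep (e.g.
#'   `c(1955, 1965, 1975, 1985)`).
#' @return `path`, invisibly.
#' @export
export_surface <- function(surface, path, cohorts = NULL) {
  stopifnot(is.data.frame(surface))
  if (!is.null(cohorts)) {
    surface <- surface[surface$birth_year %in% cohorts, , drop = FALSE]
  }
  out <- as.data.frame(lapply(surface, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
plot.apc_surface <- function(x, type = c("heatmap", "cohorts"),
                             cohorts = NULL, main = NULL, ...) {
  type <- match.arg(type)
  if (type == "heatmap") {
    yrs <- sort(unique(x$year)); ages <- sort(unique(x$age))
    z <- matrix(NA_real_, length(yrs), length(ages))
    z[cbind(match(x$year, yrs), match(x$age, ages))] <- x$estimate
    graphics::image(yrs, ages, z, xlab = "calendar year", ylab = "age",
                    col = grDevices::hcl.colors(64, "viridis"),
                    main = if (is.null(main)) attr(x, "estimand") else main,
                    ...)
  } else {
    if (is.null(cohorts)) {
      cohorts <- unique(x$birth_year[x$birth_year %% 10 == 5])
      if (!length(cohorts)) cohorts <- utils::head(unique(x$birth_year), 4L)
    }
    sub <- x[x$birth_year %in% cohorts, , drop = FALSE]
    graphics::matplot(NA, NA, xlim = range(sub$year),
                      ylim = range(c(sub$lower, sub$upper)),
                      xlab = "calendar year", ylab = "expected visits",
                      main = if (is.null(main)) attr(x, "estimand") else main,
                      type = "n", ...)
    for (i in seq_along(cohorts)) {
      ss <- sub[sub$birth_year == cohorts[i], , drop = FALSE]
      graphics::polygon(c(ss$year, rev(ss$year)),
                        c(ss$lower, rev(ss$upper)),
                        col = grDevices::adjustcolor(i + 1L, 0.2),
                        border = NA)
      graphics::lines(ss$year, ss$estimate, col = i + 1L, lwd = 2)
    }
    graphics::legend("topleft", legend = cohorts, col = seq_along(cohorts) + 1L,
                     lwd = 2, bty = "n", title = "birth year")
  }
  invisible(x)
}
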