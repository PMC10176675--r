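#' Log pointwise predictive density
#'
#' Computes, for each person-year row, the log predictive density of its
#' observed count under a fitted model. The Poisson likelihood is
#' integrated over the random-effect uncertainty: for a person seen in
#' training (and `person_known = TRUE`) over that person's Gaussian
#' posterior, otherwise over the population distribution N(0, sigma_u);
#' domain intercepts are treated analogously. Under the Laplace backend the
#' fixed and smooth coefficients are plugged in at their estimates and the
#' integral is evaluated by Gauss-Hermite quadrature; under the MCMC
#' backend the density is averaged over posterior draws.
#'
#' Cohort/period values outside the fitted range are clamped to the
#' boundary (constant extension of the surface) so held-out observations
#' near the edge of the observed rectangle remain scoreable.
#'
#' @param fit An `apc_fit` object.
#' @param rows Person-year rows to score (panel-format data frame with a
#'   `count` column).
#' @param person_known Use the training posterior of a person's random
#'   intercept where available (`TRUE`, default), or integrate every row
#'   over the population frailty distribution (`FALSE`).
#' @param gh_points Number of Gauss-Hermite nodes.
#' @param allow_unconverged Score from a non-converged fit anyway.
#'
#' @return Numeric vector of log predictive densities (all <= 0).
#' @export
log_pointwise_density <- function(fit, rows, person_known = TRUE,
                                  gh_points = 25L,
                                  allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "apc_fit"))
  if (!fit$converged && !allow_unconverged) {
    stop("fit did not converge; pass allow_unconverged = TRUE to override",
         call. = FALSE)
  }
  rows <- validate_panel(rows)
  y <- as.integer(rows$count)
  nd <- newdata_design(fit, rows, clamp = TRUE)

  if (fit$backend == "mcmc") {
    return(lpd_mcmc(fit, nd, y, person_known, gh_points))
  }

  p <- fit$design$pf + fit$design$pr
  nv <- fit$design$nv
  m <- nd$eta_fixed
  has_u <- length(fit$u) > 0L
  known_u <- person_known & !is.na(nd$iu) & has_u
  known_v <- !is.na(nd$iv)
  if (any(known_u)) m[known_u] <- m[known_u] + fit$u[nd$iu[known_u]]
  if (nv && any(known_v)) {
    m[known_v] <- m[known_v] + fit$b_pv[fit$v_idx][nd$iv[known_v]]
  }

  s2 <- numeric(length(y))
  if (has_u || nv) {
    Hinv <- chol2inv(fit$R)  # [H^{-1}] over the dense+domain block
    # columns of Q: indicator at the row's domain cell, minus the person's
    # scaled cross-Hessian column when that person's posterior is used
    n <- length(y)
    M <- matrix(0, p + nv, n)
    if (has_u && any(known_u)) {
      idx <- which(known_u)
      M[, idx] <- -fit$J[, nd$iu[idx], drop = FALSE] /
        rep(fit$d_u[nd$iu[idx]], each = p + nv)
      s2[idx] <- s2[idx] + 1 / fit$d_u[nd$iu[idx]]
    }
    if (nv && any(known_v)) {
      idx <- which(known_v)
      M[cbind(p + nd$iv[idx], idx)] <- M[cbind(p + nd$iv[idx], idx)] + 1
    }
    if (any(M != 0)) {
      Q <- Matrix::Matrix(M, sparse = TRUE)
      s2 <- s2 + Matrix::colSums(Q * (Hinv %*% Q))
    }
    if (has_u) s2[!known_u] <- s2[!known_u] + fit$sigma_u^2
    if (nv) s2[!known_v] <- s2[!known_v] + fit$sigma_v^2
  }

  gh <- gauss_hermite(gh_points)
  out <- numeric(length(y))
  flat <- s2 <= 0
  out[flat] <- stats::dpois(y[flat], exp(m[flat]), log = TRUE)
  if (any(!flat)) {
    idx <- which(!flat)
    eta <- outer(sqrt(2 * s2[idx]), gh$nodes) + m[idx]
    lp <- matrix(stats::dpois(y[idx], exp(eta), log = TRUE),
                 nrow = length(idx)) +
      rep(gh$logw, each = length(idx))
    mx <- apply(lp, 1L, max)
    out[idx] <- mx + log(rowSums(exp(lp - mx))) - 0.5 * log(pi)
  }
  out
}

lpd_mcmc <- function(fit, nd, y, person_known, gh_points) {
  dr <- fit$draws
  ndraw <- nrow(dr$pv)
  p <- fit$design$pf + fit$design$pr
  nv <- fit$design$nv
  gh <- gauss_hermite(gh_points)

  # linear predictor per draw, excluding random effects
  eta_d <- tcrossprod(dr$pv[, seq_len(p), drop = FALSE], nd$Xp)  # ndraw x n
  known_u <- person_known & !is.na(nd$iu)
  known_v <- !is.na(nd$iv)

  out <- numeric(length(y))
  for (i in seq_along(y)) {
    eta <- eta_d[, i]
    s2 <- numeric(ndraw)
    if (nv) {
      if (known_v[i]) eta <- eta + dr$pv[, p + nd$iv[i]]
      else s2 <- s2 + dr$sigma_v^2
    }
    if (length(fit$u)) {
      if (known_u[i]) eta <- eta + dr$u[, nd$iu[i]]
      else s2 <- s2 + dr$sigma_u^2
    }
    if (all(s2 == 0)) {
      lp <- stats::dpois(y[i], exp(eta), log = TRUE)
    } else {
      grid <- outer(sqrt(2 * s2), gh$nodes) + eta   # ndraw x gh
      lp <- apply(stats::dpois(y[i], exp(grid), log = TRUE) +
                    rep(gh$logw, each = ndraw), 1L, log_sum_exp) -
        0.5 * log(pi)
    }
    out[i] <- log_sum_exp(lp) - log(length(lp))
  }
  out
}

# Build design information for new person-year rows in a fitted model's
# parameterisation. Returns the dense design (fixed + penalised tensor
# columns), the fixed-coefficient linear predictor, and index matches of
# persons and domain cells into the training blocks (NA when unseen).
newdata_design <- function(fit, rows, clamp = FALSE) {
  pf <- fit$design$pf; pr <- fit$design$pr
  n <- nrow(rows)
  Xf <- matrix(1, n, 1L)
  nm <- fit$design$fixed_names
  if ("nilf" %in% nm) {
    Xf <- cbind(Xf, as.numeric(rows$employment_status == "nilf"))
  }
  if ("unemployed" %in% nm) {
    Xf <- cbind(Xf, as.numeric(rows$employment_status == "unemployed"))
  }
  if ("perinatal" %in% nm) Xf <- cbind(Xf, as.numeric(rows$perinatal))

  if (!is.null(fit$basis)) {
    C <- rows$birth_year; t <- rows$year
    if (clamp) {
      C <- pmin(pmax(C, fit$basis$range_C[1L]), fit$basis$range_C[2L])
      t <- pmin(pmax(t, fit$basis$range_t[1L]), fit$basis$range_t[2L])
    }
    te <- tensor_eval(fit$basis, C, t)
    if (ncol(te$Xn)) Xf <- cbind(Xf, te$Xn)
    Xp <- cbind(Xf, te$Xr)
  } else {
    Xp <- Xf
  }
  stopifnot(ncol(Xp) == pf + pr)

  iu <- match(rows$person_id, fit$design$person_levels)
  iv <- if (fit$design$nv) {
    match(paste(rows$birth_year, rows$year, sep = ":"),
          fit$design$cell_levels)
  } else rep(NA_integer_, n)

  list(Xp = Xp, iu = iu, iv = iv,
       eta_fixed = drop(Xp %*% fit$b_pv[seq_len(pf + pr)]))
}

# Gauss-Hermite nodes/weights by Golub-Welsch on the Jacobi matrix.
gauss_hermite <- function(n) {
  n <- as.integer(n)
  if (n == 1L) return(list(nodes = 0, logw = 0.5 * log(pi)))
  off <- sqrt(seq_len(n - 1L) / 2)
  Jm <- matrix(0, n, n)
  Jm[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  Jm[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  eg <- eigen(Jm, symmetric = TRUE)
  idx <- order(eg$values)
  list(nodes = eg$values[idx],
       logw = log(eg$vectors[1L, idx]^2) + 0.5 * log(pi))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
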