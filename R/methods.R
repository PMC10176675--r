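#' @export
print.apc_fit <- function(x, ...) {
  cat("Hierarchical Poisson APC model (variant: ", x$variant,
      ", backend: ", x$backend, ")\n", sep = "")
  cat(sprintf("  %d person-years, %d persons\n",
              nrow(x$panel), x$design$K))
  cat("  alpha (log baseline rate): ",
      signif(x$coefficients[["(Intercept)"]], 4), "\n", sep = "")
  if (length(x$covariates)) {
    rr <- exp(x$coefficients[x$covariates])
    cat("  relative rates: ",
        paste(sprintf("%s %.3f", names(rr), rr), collapse = ", "),
        "\n", sep = "")
  }
  cat("  sigma_u (person frailty SD): ", signif(x$sigma_u, 4), "\n", sep = "")
  if (!is.null(x$sigma_v)) {
    cat("  sigma_v (domain SD): ", signif(x$sigma_v, 4), "\n", sep = "")
  }
  if (!is.null(x$lambda)) {
    cat("  smoothing (cohort, period): ",
        paste(signif(x$lambda, 3), collapse = ", "), "\n", sep = "")
  }
  if (is.finite(x$edf)) cat("  effective df: ", round(x$edf, 1), "\n", sep = "")
  if (!x$converged) cat("  ** fit did not converge **\n")
  invisible(x)
}

#' Summarise a fitted APC model
#'
#' @param object An `apc_fit` object.
#' @param ... Unused.
#' @return A `summary.apc_fit` list: fit description, covariate relative
#'   rates with intervals, and variance/smoothing parameters.
#' @export
summary.apc_fit <- function(object, ...) {
  out <- list(
    variant = object$variant, backend = object$backend,
    n = nrow(object$panel), n_persons = object$design$K,
    alpha = object$coefficients[["(Intercept)"]],
    rates = if (length(object$covariates)) {
      covariate_relative_rates(object)
    },
    sigma_u = object$sigma_u, sigma_v = object$sigma_v,
    lambda = object$lambda, edf = object$edf,
    loglik = object$loglik_conditional, criterion = object$criterion,
    converged = object$converged
  )
  class(out) <- "summary.apc_fit"
  out
}

#' @export
print.summary.apc_fit <- function(x, ...) {
  cat("Hierarchical Poisson APC model (variant: ", x$variant,
      ", backend: ", x$backend, ")\n", sep = "")
  cat(sprintf("  %d person-years, %d persons\n", x$n, x$n_persons))
  cat("  baseline rate exp(alpha): ", signif(exp(x$alpha), 4),
      " visits/year\n", sep = "")
  if (!is.null(x$rates)) {
    cat("\nCovariate relative rates (95% interval):\n")
    tab <- x$rates
    tab[-1L] <- lapply(tab[-1L], round, 3)
    print(tab, row.names = FALSE)
  }
  cat("\n  sigma_u: ", signif(x$sigma_u, 4), sep = "")
  if (!is.null(x$sigma_v)) cat("   sigma_v: ", signif(x$sigma_v, 4), sep = "")
  if (!is.null(x$lambda)) {
    cat("   lambda: ", paste(signif(x$lambda, 3), collapse = ", "), sep = "")
  }
  cat("\n  conditional log-likelihood: ", round(x$loglik, 2), sep = "")
  if (is.finite(x$edf)) cat("   edf: ", round(x$edf, 1), sep = "")
  cat("\n")
  if (!x$converged) cat("  ** fit did not converge **\n")
  invisible(x)
}

#' @export
coef.apc_fit <- function(object, ...) object$coefficients

#' @export
logLik.apc_fit <- function(object, ...) {
  structure(object$loglik_conditional,
            df = if (is.finite(object$edf)) object$edf else NA_real_,
            nobs = nrow(object$panel), class = "logLik")
}

#' @export
fitted.apc_fit <- function(object, ...) object$fitted

#' @export
residuals.apc_fit <- function(object,
                              type = c("pearson", "deviance", "response"),
                              ...) {
  type <- match.arg(type)
  y <- object$panel$count
  mu <- object$fitted
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu),
         deviance = {
           d <- 2 * (stats::dpois(y, y, log = TRUE) -
                       stats::dpois(y, mu, log = TRUE))
           sign(y - mu) * sqrt(pmax(d, 0))
         })
}

#' Predict expected visit rates for person-year rows
#'
#' @param object An `apc_fit` object.
#' @param newdata Panel-format rows; defaults to the training panel.
#' @param type `"response"` (expected count) or `"link"` (log rate).
#' @param person `"known"` uses the estimated random intercept of persons
#'   seen in training (zero for new persons); `"reference"` sets u = 0 for
#'   everyone.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.apc_fit <- function(object, newdata = NULL,
                            type = c("response", "link"),
                            person = c("known", "reference"), ...) {
  type <- match.arg(type)
  person <- match.arg(person)
  if (is.null(newdata)) newdata <- object$panel
  nd <- newdata_design(object, validate_panel(newdata), clamp = FALSE)
  eta <- nd$eta_fixed
  nv <- object$design$nv
  if (nv) {
    seen <- !is.na(nd$iv)
    eta[seen] <- eta[seen] + object$b_pv[object$v_idx][nd$iv[seen]]
  }
  if (person == "known" && length(object$u)) {
    seen <- !is.na(nd$iu)
    eta[seen] <- eta[seen] + object$u[nd$iu[seen]]
  }
  if (type == "link") eta else exp(eta)
}

#' Simulate visit counts from a fitted model
#'
#' Draws Poisson counts at the fitted conditional means (estimated random
#' intercepts included), one column per requested replicate.
#'
#' @param object An `apc_fit` object.
#' @param nsim Number of replicates.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated counts, one row per
#'   training person-year.
#' @export
simulate.apc_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  mu <- object$fitted
  sim_one <- function() stats::rpois(length(mu), mu)
  out <- if (is.null(seed)) {
    replicate(nsim, sim_one())
  } else {
    with_seed(seed, replicate(nsim, sim_one()))
  }
  out <- as.data.frame(matrix(out, ncol = nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot the fitted cohort-period surface
#'
#' Heatmap of the reference-person expected visit surface (see
#' [reference_surface()]).
#'
#' @param x An `apc_fit` object.
#' @param estimand Passed to [reference_surface()].
#' @param ... Passed to [plot.apc_surface()].
#' @export
plot.apc_fit <- function(x, estimand = "median_person", ...) {
  surf <- reference_surface(x, estimand = estimand,
                            allow_unconverged = TRUE)
  plot(surf, ...)
}
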