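#' Assign cross-validation folds
#'
#' Random observation-level partition of the panel into `k` near-equal
#' folds, stratified by person: each person's rows are cycled through
#' consecutive fold labels so they spread over as many folds as possible,
#' keeping every person's random intercept estimable from the training
#' folds. Deterministic given `seed`; the global RNG state is untouched.
#'
#' @param panel Person-year panel.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold labels (1..k), one per panel row; fold
#'   sizes differ by at most one.
#' @export
make_folds <- function(panel, k = 5L, seed = 1L) {
  panel <- validate_panel(panel)
  k <- as.integer(k)
  n <- nrow(panel)
  if (k < 2L) stop("'k' must be at least 2", call. = FALSE)
  if (k > n) stop("more folds than panel rows", call. = FALSE)
  with_seed(seed, {
    labels <- sample(k)                       # random label ordering
    persons <- sample(unique(panel$person_id))  # random person order
    row_order <- order(match(panel$person_id, persons))
    folds <- integer(n)
    folds[row_order] <- rep_len(labels, n)
    folds
  })
}

#' Compare model variants by k-fold cross-validated elppd
#'
#' For each fold, refits every model specification on the remaining folds
#' and scores the held-out observations with [log_pointwise_density()]
#' (`person_known = TRUE`: a person's training rows inform their random
#' intercept). The expected log pointwise predictive density (elppd) of a
#' model is the sum of its held-out log densities over all observations;
#' identical fold splits are used for every model so comparisons are fair.
#' Pairwise elppd differences are reported with the standard error
#' sqrt(n * var(pointwise differences)).
#'
#' @param panel Person-year panel.
#' @param specs Named list of model specifications; each element is a list
#'   of arguments to [apc_fit()] (e.g. `list(variant = "smooth")`).
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @param control Shared [apc_control()] for all fits.
#' @param ... Further arguments passed to every [apc_fit()] call (e.g.
#'   `covariates`, `k` basis dimensions).
#'
#' @return Object of class `apc_cv`: `folds`, per-observation log density
#'   matrix `lpd` (rows = panel rows, columns = models), named `elppd`
#'   vector, and `pairs` data frame (`model_a`, `model_b`, `diff`, `se`).
#' @export
kfold_elppd <- function(panel, specs, k = 5L, seed = 1L,
                        control = apc_control(), ...) {
  panel <- validate_panel(panel)
  if (!length(specs)) stop("'specs' must be non-empty", call. = FALSE)
  if (is.null(names(specs)) || any(names(specs) == "")) {
    names(specs) <- vapply(specs, function(s) {
      if (!is.null(s$variant)) s$variant else "model"
    }, character(1L))
    names(specs) <- make.unique(names(specs))
  }
  folds <- make_folds(panel, k, seed)

  lpd <- matrix(NA_real_, nrow(panel), length(specs),
                dimnames = list(NULL, names(specs)))
  for (f in seq_len(k)) {
    train <- panel[folds != f, , drop = FALSE]
    test <- panel[folds == f, , drop = FALSE]
    for (m in seq_along(specs)) {
      args <- c(list(panel = train), specs[[m]],
                list(control = control), list(...))
      fit <- do.call(apc_fit, args)
      if (!fit$converged) {
        stop("fold ", f, ", model '", names(specs)[m],
             "': fit did not converge", call. = FALSE)
      }
      lpd[folds == f, m] <- log_pointwise_density(fit, test,
                                                  person_known = TRUE)
    }
  }

  elppd <- colSums(lpd)
  pairs <- NULL
  if (length(specs) > 1L) {
    cmb <- utils::combn(length(specs), 2L)
    pairs <- data.frame(
      model_a = names(specs)[cmb[1L, ]],
      model_b = names(specs)[cmb[2L, ]],
      diff = NA_real_, se = NA_real_,
      stringsAsFactors = FALSE
    )
    for (j in seq_len(ncol(cmb))) {
      di <- lpd[, cmb[1L, j]] - lpd[, cmb[2L, j]]
      pairs$diff[j] <- sum(di)
      pairs$se[j] <- sqrt(length(di) * stats::var(di))
    }
  }

  out <- list(folds = folds, lpd = lpd, elppd = elppd, pairs = pairs,
              k = k, n = nrow(panel))
  class(out) <- "apc_cv"
  out
}

#' @export
print.apc_cv <- function(x, ...) {
  cat(x$k, "-fold cross-validated elppd over ", x$n, " observations\n\n",
      sep = "")
  print(round(x$elppd, 2))
  if (!is.null(x$pairs)) {
    cat("\nPairwise differences (model_a - model_b):\n")
    tab <- x$pairs
    tab$diff <- round(tab$diff, 2)
    tab$se <- round(tab$se, 2)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}
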