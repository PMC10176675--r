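#' Evaluate a B-spline basis
#'
#' Cox-de Boor B-spline basis values on an equally-replicated knot vector.
#' Rows sum to one (partition of unity). Points outside the boundary knots
#' are an error: the fitted surface is never extrapolated.
#'
#' @param x Numeric vector of evaluation points.
#' @param knots Full knot vector (boundary knots replicated `degree` times),
#'   non-decreasing, as produced by [bspline_knots()].
#' @param degree Spline degree (3 = cubic).
#'
#' @return Matrix of dimension `length(x)` x (`length(knots) - degree - 1`).
#' @export
bspline_eval <- function(x, knots, degree = 3L) {
  degree <- as.integer(degree)
  stopifnot(degree >= 0L, !is.unsorted(knots))
  lo <- knots[degree + 1L]
  hi <- knots[length(knots) - degree]
  if (any(x < lo | x > hi)) {
    stop("evaluation points outside the boundary knots [", lo, ", ", hi,
         "]; the surface is not extrapolated", call. = FALSE)
  }
  # splineDesign treats the right boundary as exclusive; nudge boundary
  # points inside by the B-spline right-continuity convention
  xx <- pmin(x, hi - (hi - lo) * 1e-12)
  M <- splines::splineDesign(knots, xx, ord = degree + 1L, outer.ok = FALSE)
  M
}

#' Equally spaced knot vector with replicated boundaries
#'
#' @param x Data whose observed range sets the boundary knots.
#' @param k Number of basis functions.
#' @param degree Spline degree.
#' @return Numeric knot vector of length `k + degree + 1`.
#' @export
bspline_knots <- function(x, k, degree = 3L) {
  k <- as.integer(k); degree <- as.integer(degree)
  stopifnot(k >= degree + 1L)
  r <- range(x)
  if (r[1] == r[2]) stop("cannot place knots: all values identical", call. = FALSE)
  inner <- seq(r[1], r[2], length.out = k - degree + 1L)
  c(rep(r[1], degree), inner, rep(r[2], degree))
}

#' Difference penalty matrix
#'
#' The P-spline roughness penalty D'D, where D is the `order`-th difference
#' operator on adjacent B-spline coefficients. Symmetric positive
#' semi-definite with rank `k - order`; its null space holds polynomial
#' coefficient sequences up to degree `order - 1`, which therefore go
#' unpenalised (for `order = 2`, constant and linear trends are free).
#'
#' @param k Basis dimension (`k > order`).
#' @param order Difference order (default 2).
#' @return `k` x `k` penalty matrix.
#' @export
difference_penalty <- function(k, order = 2L) {
  k <- as.integer(k); order <- as.integer(order)
  if (k <= order) stop("'k' must exceed the penalty order", call. = FALSE)
  D <- diff(diag(k), differences = order)
  crossprod(D)
}

#' Tensor-product P-spline basis for the cohort x period surface
#'
#' Builds the finite linear representation of the smooth surface s(C, t)
#' over birth cohort and calendar period: marginal cubic B-spline bases on
#' equally spaced knots over the observed ranges, their row-wise Kronecker
#' (tensor) product, and two expanded difference penalties (one per margin,
#' each the Kronecker product of a marginal penalty with the other margin's
#' identity) enabling anisotropic smoothing. A sum-to-zero-over-data
#' constraint is absorbed by a column transform so the surface is orthogonal
#' to the global intercept, and the joint penalty null space (the bilinear
#' functions of C and t that no difference penalty touches) is split off
#' into unpenalised columns.
#'
#' Because age = period - cohort, the unpenalised linear span is exactly the
#' non-identifiable age/period/cohort linear trend: only the total surface
#' alpha + s(C, t) is ever reported, never separated A/P/C trends.
#'
#' @param panel Person-year panel (columns `birth_year`, `year`), or any
#'   data frame with those columns.
#' @param k_cohort,k_period Marginal basis dimensions (default 8).
#' @param degree Spline degree (default cubic).
#' @param penalty_order Difference-penalty order (default 2).
#'
#' @return Object of class `apc_basis`: marginal knot vectors, constraint
#'   and null-space transforms, penalised-column penalties `A1` (cohort
#'   roughness) and `A2` (period roughness), and the design columns for the
#'   panel rows (`Xn` unpenalised, `Xr` penalised).
#' @export
tensor_basis <- function(panel, k_cohort = 8L, k_period = 8L, degree = 3L,
                         penalty_order = 2L) {
  stopifnot(is.data.frame(panel), nrow(panel) > 0L,
            all(c("birth_year", "year") %in% names(panel)))
  k_cohort <- as.integer(k_cohort); k_period <- as.integer(k_period)
  if (k_cohort < penalty_order + 1L || k_period < penalty_order + 1L) {
    stop("marginal basis dimensions must exceed the penalty order",
         call. = FALSE)
  }
  C <- panel$birth_year; t <- panel$year
  if (length(unique(C)) < k_cohort) {
    stop("fewer distinct cohort values (", length(unique(C)), ") than ",
         "k_cohort = ", k_cohort, "; reduce k_cohort", call. = FALSE)
  }
  if (length(unique(t)) < k_period) {
    stop("fewer distinct period values (", length(unique(t)), ") than ",
         "k_period = ", k_period, "; reduce k_period", call. = FALSE)
  }

  knots_C <- bspline_knots(C, k_cohort, degree)
  knots_t <- bspline_knots(t, k_period, degree)
  BC <- bspline_eval(C, knots_C, degree)
  Bt <- bspline_eval(t, knots_t, degree)
  B <- rowwise_kronecker(BC, Bt)           # n x (k_C * k_t)

  SC <- difference_penalty(k_cohort, penalty_order)
  St <- difference_penalty(k_period, penalty_order)
  P1 <- SC %x% diag(k_period)              # cohort-direction roughness
  P2 <- diag(k_cohort) %x% St              # period-direction roughness

  # absorb the sum-to-zero-over-data constraint: theta = Zc theta_c
  cvec <- colSums(B)
  Zc <- qr.Q(qr(matrix(cvec, ncol = 1L)), complete = TRUE)[, -1L, drop = FALSE]
  P1c <- crossprod(Zc, P1 %*% Zc)
  P2c <- crossprod(Zc, P2 %*% Zc)

  # split the joint penalty null space (unpenalised, fixed) from the
  # penalised range space
  eg <- eigen(P1c + P2c, symmetric = TRUE)
  tol <- max(eg$values) * 1e-9
  null_idx <- which(eg$values < tol)
  range_idx <- setdiff(seq_along(eg$values), null_idx)
  Ur <- eg$vectors[, range_idx, drop = FALSE]
  Un <- eg$vectors[, null_idx, drop = FALSE]
  A1 <- sym(crossprod(Ur, P1c %*% Ur))
  A2 <- sym(crossprod(Ur, P2c %*% Ur))

  Bc <- B %*% Zc
  out <- list(
    knots_C = knots_C, knots_t = knots_t, degree = degree,
    penalty_order = penalty_order,
    k_cohort = k_cohort, k_period = k_period,
    Zc = Zc, Ur = Ur, Un = Un, A1 = A1, A2 = A2,
    Xr = Bc %*% Ur, Xn = Bc %*% Un,
    # raw (untransformed) tensor design and the map from the constrained
    # [null | range] coefficients back to raw coefficients; the raw basis
    # is sparse (few B-splines overlap any point), which the fitting
    # engine exploits
    B_raw = B, Ttens = Zc %*% cbind(Un, Ur),
    range_C = range(C), range_t = range(t)
  )
  class(out) <- "apc_basis"
  out
}

#' Evaluate the tensor basis design at new cohort/period points
#'
#' @param basis An `apc_basis` object.
#' @param birth_year,year Vectors of equal length (recycled) inside the
#'   observed ranges.
#' @return List with matrices `Xn` (unpenalised columns) and `Xr`
#'   (penalised columns) matching the fitted parameterisation.
#' @export
tensor_eval <- function(basis, birth_year, year) {
  stopifnot(inherits(basis, "apc_basis"))
  n <- max(length(birth_year), length(year))
  birth_year <- rep_len(birth_year, n); year <- rep_len(year, n)
  BC <- bspline_eval(birth_year, basis$knots_C, basis$degree)
  Bt <- bspline_eval(year, basis$knots_t, basis$degree)
  Bc <- rowwise_kronecker(BC, Bt) %*% basis$Zc
  list(Xn = Bc %*% basis$Un, Xr = Bc %*% basis$Ur)
}

# Row-wise Kronecker (face-splitting) product: row i is A[i,] %x% B[i,].
rowwise_kronecker <- function(A, B) {
  ka <- ncol(A); kb <- ncol(B)
  out <- matrix(0, nrow(A), ka * kb)
  for (j in seq_len(ka)) {
    out[, (j - 1L) * kb + seq_len(kb)] <- A[, j] * B
  }
  out
}

sym <- function(M) (M + t(M)) / 2
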