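#' Built-in ground-truth cohort-period surfaces
#'
#' Named smooth functions g(C, t) on the cohort x period rectangle used as
#' simulation ground truth for the log-rate surface. All are bounded and
#' smooth; `"flat"` is identically zero and `"age_linear"` depends on
#' (C, t) only through age t - C, so a correctly fitted model attributes it
#' entirely to ageing.
#'
#' Available surfaces:
#' \describe{
#'   \item{flat}{g = 0.}
#'   \item{age_linear}{g = `slope` * (age - `center`); default slope 0.02
#'     per year of age, centred at age 40.}
#'   \item{age_quadratic}{linear plus quadratic trend in (age - center)/10
#'     decades; mild curvature typical of adult primary-care use.}
#'   \item{cohort_ridge}{Gaussian bump in birth cohort centred on 1970.}
#'   \item{u_shape}{quadratic valley in calendar year with an interior
#'     minimum (default 2009) for every cohort.}
#' }
#'
#' @param name Surface name, one of `"flat"`, `"age_linear"`,
#'   `"age_quadratic"`, `"cohort_ridge"`, `"u_shape"`.
#' @param ... Optional overrides of the shape constants (`slope`, `center`,
#'   `lin`, `quad`, `height`, `ridge_center`, `ridge_width`, `depth`,
#'   `valley_center`, `valley_width` depending on the surface).
#'
#' @return A vectorised function `g(C, t)` returning the log-rate offset.
#' @export
#' @examples
#' g <- builtin_surface("age_linear", slope = 0.03)
#' g(1970, 2010) - g(1970, 2009)  # equals the slope
builtin_surface <- function(name, ...) {
  opts <- list(...)
  pick <- function(key, default) if (!is.null(opts[[key]])) opts[[key]] else default
  switch(
    name,
    flat = function(C, t) rep(0, length.out = max(length(C), length(t))),
    age_linear = {
      slope <- pick("slope", 0.02); center <- pick("center", 40)
      function(C, t) slope * ((t - C) - center)
    },
    age_quadratic = {
      lin <- pick("lin", 0.15); quad <- pick("quad", 0.08)
      center <- pick("center", 40)
      function(C, t) {
        a <- ((t - C) - center) / 10
        lin * a + quad * a^2
      }
    },
    cohort_ridge = {
      height <- pick("height", 0.3)
      c0 <- pick("ridge_center", 1970); w <- pick("ridge_width", 8)
      function(C, t) height * exp(-((C - c0) / w)^2) + 0 * t
    },
    u_shape = {
      depth <- pick("depth", 0.1)
      t0 <- pick("valley_center", 2009); w <- pick("valley_width", 5)
      function(C, t) depth * ((t - t0) / w)^2 + 0 * C
    },
    stop("unknown surface '", name, "'; available: flat, age_linear, ",
         "age_quadratic, cohort_ridge, u_shape", call. = FALSE)
  )
}
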