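#' Observation-time distributions
#'
#' The random-observation-time estimator scores a source hypothesis by
#' integrating the snapshot likelihood against the distribution of the
#' (independent) observation time `T`. Four families are supported: a point
#' mass (fixed observation time), exponential, uniform, and a tabulated
#' density on a grid (linearly interpolated; must integrate to 1 within
#' 1e-6 on its support).
#'
#' @param t fixed observation time (point mass), or grid of time points
#'   (tabulated).
#' @param rate rate of the exponential distribution.
#' @param a,b endpoints of the uniform distribution.
#' @param density density values on the grid `t`.
#' @return an object of class `sf_obs_time`.
#' @examples
#' obs_time_exp(1)
#' obs_time_unif(0, 5)
#' @export
obs_time_point <- function(t) {
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0)
  structure(list(kind = "point", t = t), class = "sf_obs_time")
}

#' @rdname obs_time_point
#' @export
obs_time_exp <- function(rate) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate > 0)
  structure(list(kind = "exponential", rate = rate), class = "sf_obs_time")
}

#' @rdname obs_time_point
#' @export
obs_time_unif <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L,
            0 <= a, a < b)
  structure(list(kind = "uniform", a = a, b = b), class = "sf_obs_time")
}

#' @rdname obs_time_point
#' @export
obs_time_grid <- function(t, density) {
  stopifnot(is.numeric(t), is.numeric(density), length(t) == length(density),
            length(t) >= 2L, all(diff(t) > 0), all(t >= 0), all(density >= 0))
  z <- sum(diff(t) * (utils::head(density, -1L) + utils::tail(density, -1L)) / 2)
  if (abs(z - 1) > 1e-6) {
    stop(sprintf("tabulated density integrates to %.8f, expected 1 within 1e-6", z),
         call. = FALSE)
  }
  structure(list(kind = "grid", t = t, density = density),
            class = "sf_obs_time")
}

#' @export
print.sf_obs_time <- function(x, ...) {
  desc <- switch(x$kind,
                 point = sprintf("point mass at t = %g", x$t),
                 exponential = sprintf("Exponential(rate = %g)", x$rate),
                 uniform = sprintf("Uniform(%g, %g)", x$a, x$b),
                 grid = sprintf("tabulated on %d grid points", length(x$t)))
  cat("observation-time distribution:", desc, "\n")
  invisible(x)
}

# E_T[f(T)] by adaptive quadrature; f need not be vectorized
sf_obs_time_expectation <- function(f, dist, rel_tol = 1e-8) {
  fv <- Vectorize(f)
  switch(dist$kind,
    point = f(dist$t),
    exponential = {
      q <- stats::integrate(function(t) fv(t) * stats::dexp(t, dist$rate),
                            0, Inf, rel.tol = rel_tol, stop.on.error = FALSE)
      if (q$message != "OK" && q$abs.error > rel_tol * max(1, abs(q$value))) {
        stop(sprintf("observation-time quadrature did not converge: %s", q$message),
             call. = FALSE)
      }
      q$value
    },
    uniform = {
      q <- stats::integrate(fv, dist$a, dist$b, rel.tol = rel_tol,
                            stop.on.error = FALSE)
      if (q$message != "OK" && q$abs.error > rel_tol * max(1, abs(q$value))) {
        stop(sprintf("observation-time quadrature did not converge: %s", q$message),
             call. = FALSE)
      }
      q$value / (dist$b - dist$a)
    },
    grid = {
      vals <- fv(dist$t) * dist$density
      sum(diff(dist$t) * (utils::head(vals, -1L) + utils::tail(vals, -1L)) / 2)
    },
    stop("unknown observation-time kind", call. = FALSE))
}
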