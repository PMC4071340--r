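#' General N-component network specification
#'
#' Describe an N-component gene network whose genes share one
#' transcriptional centre: each protein obeys
#' \deqn{dx_i/dt = (1+\delta)\,\theta_i f(\rho, x_1, \dots, x_N) - \gamma x_i}
#' where `f` is the centre's fractional activity (bounded in `[0, 1]`),
#' `theta_i` the maximal expression rates, `gamma` the cell-division
#' (dilution) rate, `rho` an external control parameter, and `delta` a
#' parallel dosage perturbation applied to every gene at once.
#'
#' @param n_components Number of network genes (>= 1).
#' @param f Activity function `f(rho, x)` taking the control parameter
#'   and the state vector `x` (length `n_components`), returning a
#'   value in `[0, 1]`.
#' @param theta Maximal expression rates (positive, length
#'   `n_components`).
#' @param gamma Cell-division rate (> 0).
#' @param rho External control parameter passed through to `f`.
#' @param delta Parallel dosage perturbation (>= -1).
#' @param gradient Optional analytic gradient `function(rho, x)`
#'   returning the vector of partials of `f`; when absent, partials are
#'   taken by central differences with relative step `1e-6`.
#' @return A list of class `"network_spec"`.
#' @examples
#' spec <- network_spec(1, function(rho, x) x / (1 + x), theta = 2, gamma = 1)
#' steady_states(spec)
#' @export
network_spec <- function(n_components, f, theta, gamma, rho = 1,
                         delta = 0, gradient = NULL) {
  stopifnot(n_components >= 1, n_components == as.integer(n_components),
            is.function(f), length(theta) == n_components,
            all(theta > 0), gamma > 0, delta >= -1)
  structure(list(
    n = as.integer(n_components), f = f, theta = as.numeric(theta),
    gamma = gamma, rho = rho, delta = delta, gradient = gradient
  ), class = "network_spec")
}

# state vector from the scalar unknown x1, using the steady-state
# proportionality x_m = (theta_m / theta_1) x_1
state_from_x1 <- function(spec, x1) x1 * spec$theta / spec$theta[1]

#' Steady states of an N-component network
#'
#' At steady state every component is proportional to the first
#' (`x_m = theta_m x_1 / theta_1`), reducing the fixed-point problem to
#' the scalar equation
#' `x_1 = (1 + delta) (theta_1 / gamma) f(rho, x(x_1))`. The equation
#' is solved by a sign-change scan over `[0, (1+delta) theta_1/gamma]`
#' (1024 intervals) followed by bisection refinement; with `f` bounded
#' in `[0, 1]` the interval always brackets at least one root. All
#' roots found are returned; under bistability downstream consumers
#' must select a branch explicitly.
#'
#' @param spec A [network_spec()].
#' @param n_scan Number of scan intervals.
#' @param tol Relative bisection tolerance.
#' @return A list of steady-state vectors, ascending in `x_1`.
#' @export
steady_states <- function(spec, n_scan = 1024L, tol = 1e-10) {
  stopifnot(inherits(spec, "network_spec"))
  scale <- (1 + spec$delta) * spec$theta[1] / spec$gamma
  resid <- function(x1) {
    x1 - (1 + spec$delta) * (spec$theta[1] / spec$gamma) *
      spec$f(spec$rho, state_from_x1(spec, x1))
  }
  upper <- max(scale, .Machine$double.eps)
  xs <- seq(0, upper * (1 + 1e-9), length.out = n_scan + 1L)
  rs <- vapply(xs, resid, numeric(1))
  roots <- numeric(0)
  for (j in seq_len(n_scan)) {
    r1 <- rs[j]; r2 <- rs[j + 1]
    if (r1 == 0) {
      roots <- c(roots, xs[j])
    } else if (r1 * r2 < 0) {
      root <- stats::uniroot(resid, c(xs[j], xs[j + 1]),
                             tol = tol * max(upper, 1))$root
      roots <- c(roots, root)
    }
  }
  if (rs[length(rs)] == 0) roots <- c(roots, xs[length(xs)])
  # de-duplicate near-identical roots from adjacent intervals
  roots <- sort(roots)
  if (length(roots) > 1) {
    keep <- c(TRUE, diff(roots) > 1e-7 * max(upper, 1))
    roots <- roots[keep]
  }
  lapply(roots, function(x1) state_from_x1(spec, x1))
}

# partials of f at x: analytic if registered, else central differences
f_partials <- function(spec, x, rel_step = 1e-6) {
  if (!is.null(spec$gradient)) {
    return(as.numeric(spec$gradient(spec$rho, x)))
  }
  vapply(seq_len(spec$n), function(j) {
    h <- rel_step * max(abs(x[j]), 1)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- max(x[j] - h, 0)
    (spec$f(spec$rho, xp) - spec$f(spec$rho, xm)) / (xp[j] - xm[j])
  }, numeric(1))
}

#' Sensitivity of network activity to parallel dosage change
#'
#' The derivative of the activity `f` with respect to the parallel
#' dosage perturbation `delta`, evaluated at a steady state:
#' \deqn{\frac{df}{d\delta} =
#'   \frac{\left[\sum_i \theta_i \partial f/\partial x_i\right] f}
#'        {\gamma - (1+\delta) \sum_i \theta_i \partial f/\partial x_i}}
#' A value of zero means the network activity is invariant to
#' network-dosage changes (perfect compensation) at that state.
#'
#' @param spec A [network_spec()].
#' @param x_star A steady state of `spec` (from [steady_states()]).
#' @return A list: `value` (the derivative), `weighted_sum`
#'   (`sum theta_i df/dx_i`), `singular` (`TRUE` when the denominator
#'   is within `1e-12` of zero, marginal stability, and `value` is
#'   `NA`).
#' @export
dosage_sensitivity <- function(spec, x_star) {
  stopifnot(inherits(spec, "network_spec"), length(x_star) == spec$n)
  partials <- f_partials(spec, x_star)
  w <- sum(spec$theta * partials)
  fval <- spec$f(spec$rho, x_star)
  denom <- spec$gamma - (1 + spec$delta) * w
  if (abs(denom) < 1e-12 * max(spec$gamma, abs(w), 1)) {
    return(list(value = NA_real_, weighted_sum = w, singular = TRUE))
  }
  list(value = w * fval / denom, weighted_sum = w, singular = FALSE)
}

#' Necessary-condition check for dosage compensation
#'
#' For `df/ddelta` to vanish identically, the weighted sum
#' `sum theta_i df/dx_i` must be zero; since all `theta_i` are
#' positive, at least one partial must be positive and at least one
#' negative. A network whose nonzero partials all share one sign
#' (components of the same regulatory sign) therefore cannot be
#' dosage-compensated.
#'
#' @inheritParams dosage_sensitivity
#' @param zero_tol Partials with absolute value below `zero_tol` count
#'   as zero.
#' @return A list of class `"necessary_condition"`: `partials`,
#'   `signs`, `weighted_sum` and `verdict` (one of
#'   `"compensation impossible (same-sign components)"`,
#'   `"compensation possible"`, `"degenerate (all partials zero)"`).
#' @export
necessary_condition_check <- function(spec, x_star, zero_tol = 1e-12) {
  stopifnot(inherits(spec, "network_spec"), length(x_star) == spec$n)
  partials <- f_partials(spec, x_star)
  signs <- sign(partials)
  signs[abs(partials) < zero_tol] <- 0
  verdict <- if (all(signs == 0)) {
    "degenerate (all partials zero)"
  } else if (any(signs > 0) && any(signs < 0)) {
    "compensation possible"
  } else {
    "compensation impossible (same-sign components)"
  }
  structure(list(
    partials = partials, signs = signs,
    weighted_sum = sum(spec$theta * partials), verdict = verdict
  ), class = "necessary_condition")
}

#' @export
print.necessary_condition <- function(x, ...) {
  cat("Partial-derivative signs:", paste(x$signs, collapse = " "), "\n")
  cat("Weighted sum sum(theta_i df/dx_i):",
      format(x$weighted_sum, digits = 6), "\n")
  cat("Verdict:", x$verdict, "\n")
  invisible(x)
}
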