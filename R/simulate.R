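#' Kinetic parameters of the induction dynamics
#'
#' Production, dilution and degradation parameters for the
#' activator/inhibitor induction dynamics. Degradation rate constants
#' are derived from protein half-lives as `gamma = ln(2) / t_half`,
#' with an infinite half-life (a stable protein) giving `gamma = 0`.
#'
#' @param theta_a,theta_i Maximal production rates, proteins/hour.
#' @param gamma_0 Dilution rate constant, 1/hour (cell-division rate).
#' @param t_half_a,t_half_i Protein half-lives in minutes; `Inf` means
#'   a stable protein.
#' @param lambda_a,lambda_i Basal production coefficients in `[0, 1]`:
#'   the fraction of maximal production sustained at zero activity.
#' @param N Network copy number (positive integer).
#' @return A list of class `"kinetic_params"` with the derived
#'   `gamma_a` and `gamma_i` (1/hour) included.
#' @examples
#' kinetic_params(theta_a = 300, theta_i = 1500, t_half_a = Inf, t_half_i = 30)
#' @export
kinetic_params <- function(theta_a = 300, theta_i = 300, gamma_0 = 0.46,
                           t_half_a = Inf, t_half_i = Inf,
                           lambda_a = 0.20, lambda_i = 0.20, N = 1L) {
  stopifnot(theta_a >= 0, theta_i >= 0, gamma_0 > 0,
            t_half_a > 0, t_half_i > 0,
            lambda_a >= 0, lambda_a <= 1, lambda_i >= 0, lambda_i <= 1,
            N >= 1, N == as.integer(N))
  halflife_to_gamma <- function(t_half) {
    if (is.infinite(t_half)) 0 else log(2) / (t_half / 60)
  }
  structure(list(
    theta_a = theta_a, theta_i = theta_i, gamma_0 = gamma_0,
    t_half_a = t_half_a, t_half_i = t_half_i,
    gamma_a = halflife_to_gamma(t_half_a),
    gamma_i = halflife_to_gamma(t_half_i),
    lambda_a = lambda_a, lambda_i = lambda_i, N = as.integer(N)
  ), class = "kinetic_params")
}

#' Default logarithmic inducer grid
#'
#' The canonical induction grid `g = 10^(-2 + 0.025 C)` for
#' `C = 0, 1, ..., 80`: 81 strictly increasing points spanning
#' `[0.01, 1]`.
#'
#' @param C Integer sequence of grid indices.
#' @return Numeric vector of inducer levels.
#' @export
inducer_grid <- function(C = 0:80) {
  stopifnot(length(C) >= 1, all(C == as.integer(C)))
  10^(-2 + 0.025 * C)
}

#' Basal steady state
#'
#' Steady protein concentrations under basal transcription, used as the
#' initial condition for induction time courses. With production
#' `N theta lambda` and first-order loss `(gamma_0 + gamma) x`, the
#' fixed point is `x0 = N theta lambda / (gamma_0 + gamma)`.
#'
#' The copy-number factor `N` is included by default so that the basal
#' state is the true fixed point of the `N`-copy dynamics at basal
#' activity; `literal = TRUE` drops the factor (the single-copy
#' convention some analyses adopt regardless of `N`).
#'
#' @param k A [kinetic_params()] object.
#' @param literal If `TRUE`, omit the `N` factor.
#' @return Named numeric vector `c(a = a0, i = i0)`.
#' @examples
#' basal_state(kinetic_params(theta_a = 300, lambda_a = 0.2)) # a0 = 60/0.46
#' @export
basal_state <- function(k, literal = FALSE) {
  stopifnot(inherits(k, "kinetic_params"))
  Nf <- if (literal) 1 else k$N
  c(a = Nf * k$theta_a * k$lambda_a / (k$gamma_0 + k$gamma_a),
    i = Nf * k$theta_i * k$lambda_i / (k$gamma_0 + k$gamma_i))
}

# parameter vector handed to the compiled derivative function; the g
# grid occupies a fixed-size block after the 15 leading slots so the
# vector length always matches the DLL's parameter table
# (see src/dosage_ode.c)
MAX_GRID <- 512L

ode_parms <- function(form, p, k, g) {
  G <- length(g)
  if (G > MAX_GRID) stop("inducer grid longer than ", MAX_GRID, call. = FALSE)
  form_code <- match(form, TOPOLOGY_FORMS)
  c(form_code, p$S_a, p$S_i, p$alpha, p$beta, p$const_level,
    k$N, k$theta_a, k$theta_i, k$lambda_a, k$lambda_i,
    k$gamma_0, k$gamma_a, k$gamma_i, G, g,
    numeric(MAX_GRID - G))
}

# integrate the induction dynamics for every g in parallel (independent
# 2-ODE blocks) in one lsoda call; returns matrix with columns a, i
integrate_grid <- function(form, p, k, g, t_end = 24,
                           literal_basal = FALSE,
                           rtol = 1e-6, atol = 1e-9) {
  G <- length(g)
  y0 <- rep(basal_state(k, literal = literal_basal), times = G)
  out <- tryCatch(
    deSolve::lsoda(
      y = y0, times = c(0, t_end), func = "dosage_derivs",
      parms = ode_parms(form, p, k, g), dllname = "netdosage",
      initfunc = "dosage_initmod", rtol = rtol, atol = atol,
      jactype = "bandint", bandup = 1L, banddown = 1L, maxsteps = 10000L
    ),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(out) || nrow(out) < 2L || anyNA(out[nrow(out), -1])) {
    return(matrix(NA_real_, nrow = G, ncol = 2,
                  dimnames = list(NULL, c("a", "i"))))
  }
  matrix(out[nrow(out), -1], ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("a", "i")))
}

#' Integrate the induction dynamics for one inducer level
#'
#' Numerically integrate the two-component induction dynamics
#' \deqn{da/dt = N \theta_a [\lambda_a (1 - f) + f] - \gamma_0 a - \gamma_a a}
#' (and the analogous inhibitor equation), with
#' `f = activity(form, p, g, a, i)`, from the basal steady state to
#' `t_end` hours.
#'
#' @inheritParams activity
#' @param k A [kinetic_params()] object.
#' @param g Inducer level (scalar).
#' @param t_end Integration horizon in hours.
#' @param literal_basal Passed to [basal_state()].
#' @return A tibble with one row: `a_end`, `i_end`, `f_end`, `status`
#'   (`"ok"` or `"numerical_problem"`).
#' @export
integrate_network <- function(form, p, k, g, t_end = 24,
                              literal_basal = FALSE) {
  check_form(form)
  stopifnot(inherits(p, "topology_params"), inherits(k, "kinetic_params"),
            is.numeric(g), length(g) == 1L, g >= 0)
  st <- integrate_grid(form, p, k, g, t_end = t_end,
                       literal_basal = literal_basal)
  endpoint_tibble(form, p, g, st)[1, ]
}

# shared endpoint post-processing: clamp small negatives, flag problems
endpoint_tibble <- function(form, p, g, st) {
  a <- unname(st[, "a"]); i <- unname(st[, "i"])
  bad <- !is.finite(a) | !is.finite(i) | a < -1e-6 | i < -1e-6
  a <- pmax(a, 0); i <- pmax(i, 0)
  f <- rep(NA_real_, length(g))
  if (any(!bad)) {
    f[!bad] <- activity(form, p, g[!bad], a[!bad], i[!bad])
  }
  bad <- bad | !is.finite(f)
  tibble::tibble(
    g = g, a_end = a, i_end = i, f_end = f,
    status = ifelse(bad, "numerical_problem", "ok")
  )
}

#' Inducibility curve of a network
#'
#' Steady network activity `f` as a function of inducer level over a
#' logarithmic grid, obtained by integrating the induction dynamics to
#' `t_end` hours at every grid point.
#'
#' @inheritParams integrate_network
#' @param grid Inducer grid (strictly increasing, positive); defaults
#'   to [inducer_grid()].
#' @return A tibble of class `"inducibility_curve"` with columns `g`,
#'   `a_end`, `i_end`, `f_end`, `status`, and attributes `N` (copy
#'   number) and `excluded` (`TRUE` if any point had a numerical
#'   problem).
#' @examples
#' p <- topology_params(S_a = 0.1, S_i = 0.02, alpha = 1, beta = 1)
#' k <- kinetic_params(theta_a = 1500, theta_i = 1500)
#' curve <- inducibility_curve("C_seq_inhibitor", p, k, inducer_grid(seq(0, 80, 10)))
#' @export
inducibility_curve <- function(form, p, k, grid = inducer_grid(),
                               t_end = 24, literal_basal = FALSE) {
  check_form(form)
  stopifnot(inherits(p, "topology_params"), inherits(k, "kinetic_params"),
            all(grid > 0), !is.unsorted(grid, strictly = TRUE))
  st <- integrate_grid(form, p, k, grid, t_end = t_end,
                       literal_basal = literal_basal)
  out <- endpoint_tibble(form, p, grid, st)
  structure(out,
            class = c("inducibility_curve", class(out)),
            N = k$N, form = form,
            excluded = any(out$status != "ok"))
}
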