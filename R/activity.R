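#' Topology forms for two-component activator-inhibitor networks
#'
#' The package models two-component gene networks in which an activator
#' `a` and an inhibitor `i` are expressed from promoters driven by a
#' common transcriptional centre whose fractional activity is
#' `f(g, a, i)` with inducer level `g`. Three interaction topologies
#' carry distinct functional forms:
#'
#' * `"B_seq_activator"`: the inhibitor sequesters the activator; the
#'   effective activator `S_a g a / (1 + (S_i i)^beta)` drives a
#'   Hill-type activation with exponent `alpha`.
#' * `"C_seq_inhibitor"`: the activator sequesters the inhibitor (the
#'   GAL-like architecture: Gal3 titrates Gal80, Gal80 represses); the
#'   effective inhibitor `S_i i / (1 + (S_a g a)^alpha)` enters a
#'   Hill-type repression with exponent `beta`.
#' * `"D_double_direct"`: both components act directly on the
#'   transcriptional centre, as a product of an activating and a
#'   repressing Hill term.
#'
#' Two additional forms exist purely as test plumbing and do not model
#' a published topology: `"SAME_SIGN_FIXTURE"` wires two direct
#' activators together (both components share the activating sign), and
#' `"CONSTANT_FIXTURE"` returns a fixed activity level.
#'
#' @name topology_forms
#' @keywords internal
NULL

TOPOLOGY_FORMS <- c(
  "B_seq_activator", "C_seq_inhibitor", "D_double_direct",
  "SAME_SIGN_FIXTURE", "CONSTANT_FIXTURE"
)

#' Topology interaction parameters
#'
#' Bundle the four sampled interaction parameters of a two-component
#' topology: the scales of action `S_a` (activator) and `S_i`
#' (inhibitor), and the stoichiometry exponents `alpha` and `beta`
#' quantifying the nonlinearity with which each component acts.
#'
#' @param S_a Activator scale of action (> 0). Dimensionless per unit
#'   inducer times concentration.
#' @param S_i Inhibitor scale of action (> 0), per unit concentration.
#' @param alpha Activator stoichiometry exponent (> 0).
#' @param beta Inhibitor stoichiometry exponent (> 0).
#' @param const_level Activity level in `[0, 1]`, used only by the
#'   `"CONSTANT_FIXTURE"` form.
#' @return A list of class `"topology_params"`.
#' @examples
#' topology_params(S_a = 1, S_i = 1, alpha = 2, beta = 1)
#' @export
topology_params <- function(S_a = 1, S_i = 1, alpha = 1, beta = 1,
                            const_level = 0.5) {
  p <- list(S_a = S_a, S_i = S_i, alpha = alpha, beta = beta,
            const_level = const_level)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("topology parameter `", nm, "` must be a finite numeric scalar",
           call. = FALSE)
    }
  }
  if (S_a <= 0 || S_i <= 0 || alpha <= 0 || beta <= 0) {
    stop("S_a, S_i, alpha and beta must be positive", call. = FALSE)
  }
  if (const_level < 0 || const_level > 1) {
    stop("const_level must lie in [0, 1]", call. = FALSE)
  }
  structure(p, class = "topology_params")
}

check_form <- function(form) {
  if (!is.character(form) || length(form) != 1L ||
      !form %in% TOPOLOGY_FORMS) {
    stop("`form` must be one of: ", paste(TOPOLOGY_FORMS, collapse = ", "),
         call. = FALSE)
  }
  form
}

#' Network activity of a two-component topology
#'
#' Evaluate the fractional activity `f(g, a, i)` of the transcriptional
#' centre for a given topology form. All arguments after `form` and `p`
#' are vectorised and recycled to a common length.
#'
#' Limits are defined so that `f` is continuous on the closed domain:
#' for `"B_seq_activator"` the zero-effective-activator limit gives
#' `f = 0`, and for `"C_seq_inhibitor"` the zero-effective-inhibitor
#' limit gives `f = 1`. Values are clamped to `[0, 1]`; overshoot
#' beyond `1e-9` (which would indicate an evaluation bug rather than
#' floating-point noise) raises a warning.
#'
#' @param form Topology form tag; see [topology_forms].
#' @param p A [topology_params()] object.
#' @param g Inducer level (>= 0).
#' @param a Activator concentration (>= 0).
#' @param i Inhibitor concentration (>= 0).
#' @return Numeric vector of activities in `[0, 1]`.
#' @examples
#' p <- topology_params(S_a = 1, S_i = 1, alpha = 2, beta = 1)
#' activity("B_seq_activator", p, g = 1, a = 4, i = 1) # 0.8
#' activity("C_seq_inhibitor", p, g = 1, a = 1, i = 0) # 1
#' @export
activity <- function(form, p, g, a, i) {
  check_form(form)
  stopifnot(inherits(p, "topology_params"))
  n <- max(length(g), length(a), length(i))
  g <- rep_len(as.numeric(g), n)
  a <- rep_len(as.numeric(a), n)
  i <- rep_len(as.numeric(i), n)
  if (anyNA(g) || anyNA(a) || anyNA(i) ||
      any(!is.finite(g)) || any(!is.finite(a)) || any(!is.finite(i))) {
    stop("g, a and i must be finite", call. = FALSE)
  }
  if (any(g < 0) || any(a < 0) || any(i < 0)) {
    stop("g, a and i must be nonnegative", call. = FALSE)
  }
  f <- switch(form,
    B_seq_activator = {
      X <- p$S_a * g * a / (1 + (p$S_i * i)^p$beta)
      # X^(-alpha) overflows to Inf at X = 0, giving f = 0: the defined limit
      1 / (1 + X^(-p$alpha))
    },
    C_seq_inhibitor = {
      Y <- p$S_i * i / (1 + (p$S_a * g * a)^p$alpha)
      1 / (1 + Y^p$beta)
    },
    D_double_direct = {
      (1 / (1 + (p$S_a * g * a)^(-p$alpha))) *
        (1 / (1 + (p$S_i * i)^p$beta))
    },
    SAME_SIGN_FIXTURE = {
      (1 / (1 + (p$S_a * g * a)^(-p$alpha))) *
        (1 / (1 + (p$S_i * g * i)^(-p$beta)))
    },
    CONSTANT_FIXTURE = rep_len(p$const_level, n)
  )
  f[is.nan(f)] <- 0 # 0 * Inf style indeterminate limits resolve to 0
  over <- f > 1 + 1e-9 | f < -1e-9
  if (any(over)) {
    warning("activity overshot [0, 1] by more than 1e-9 at ",
            sum(over), " point(s)", call. = FALSE)
  }
  pmin(pmax(f, 0), 1)
}

#' Partial derivatives of the network activity
#'
#' Analytic partial derivatives of `f` with respect to the activator and
#' inhibitor concentrations, for use in the dosage-sensitivity analysis.
#' Derivatives are exact closed forms for all topology forms; central
#' differences are only used by the test oracle.
#'
#' @inheritParams activity
#' @return A list with elements `dfda` and `dfdi` (numeric vectors), and
#'   `boundary` (logical vector flagging evaluation at a
#'   non-differentiable domain boundary, where the one-sided limit is
#'   returned).
#' @examples
#' p <- topology_params(S_a = 1, S_i = 1, alpha = 2, beta = 1)
#' activity_gradient("B_seq_activator", p, g = 1, a = 4, i = 1)
#' @export
activity_gradient <- function(form, p, g, a, i) {
  check_form(form)
  stopifnot(inherits(p, "topology_params"))
  n <- max(length(g), length(a), length(i))
  g <- rep_len(as.numeric(g), n)
  a <- rep_len(as.numeric(a), n)
  i <- rep_len(as.numeric(i), n)
  if (any(g < 0) || any(a < 0) || any(i < 0)) {
    stop("g, a and i must be nonnegative", call. = FALSE)
  }
  al <- p$alpha; be <- p$beta; Sa <- p$S_a; Si <- p$S_i
  # Hill building blocks; u^(h-1) at u = 0 follows R's conventions
  # (0^0 = 1, 0^neg = Inf), so exponents < 1 yield Inf at the boundary,
  # which is flagged below rather than silently propagated.
  hill_act <- function(u, h) { # H(u) = 1/(1+u^-h), H(0) = 0
    H <- 1 / (1 + u^(-h)); H[u == 0] <- 0
    list(H = H, d = h * u^(h - 1) / (1 + u^h)^2)
  }
  hill_rep <- function(u, h) { # R(u) = 1/(1+u^h)
    list(R = 1 / (1 + u^h), d = -h * u^(h - 1) / (1 + u^h)^2)
  }
  res <- switch(form,
    B_seq_activator = {
      D <- 1 + (Si * i)^be
      hb <- hill_act(Sa * g * a / D, al)
      dXda <- Sa * g / D
      dXdi <- -(Sa * g * a / D^2) * be * Si * (Si * i)^(be - 1)
      dXdi[Sa * g * a == 0 & i == 0] <- 0 # X identically 0 along this edge
      list(dfda = hb$d * dXda, dfdi = hb$d * dXdi)
    },
    C_seq_inhibitor = {
      E <- 1 + (Sa * g * a)^al
      hr <- hill_rep(Si * i / E, be)
      dYdi <- Si / E
      dYda <- -(Si * i / E^2) * al * Sa * g * (Sa * g * a)^(al - 1)
      dYda[i == 0] <- 0 # Y identically 0 along a when i = 0
      list(dfda = hr$d * dYda, dfdi = hr$d * dYdi)
    },
    D_double_direct = {
      ha <- hill_act(Sa * g * a, al); hr <- hill_rep(Si * i, be)
      list(dfda = ha$d * Sa * g * hr$R, dfdi = ha$H * hr$d * Si)
    },
    SAME_SIGN_FIXTURE = {
      ha <- hill_act(Sa * g * a, al); hi <- hill_act(Si * g * i, be)
      list(dfda = ha$d * Sa * g * hi$H, dfdi = ha$H * hi$d * Si * g)
    },
    CONSTANT_FIXTURE = list(dfda = rep_len(0, n), dfdi = rep_len(0, n))
  )
  dfda <- rep_len(res$dfda, n); dfdi <- rep_len(res$dfdi, n)
  boundary <- !is.finite(dfda) | !is.finite(dfdi)
  dfda[boundary] <- NA_real_
  dfdi[boundary] <- NA_real_
  list(dfda = dfda, dfdi = dfdi, boundary = boundary)
}
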