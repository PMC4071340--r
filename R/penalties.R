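#' Reference inducibility curve
#'
#' A Hill-shaped target curve describing what a "well-behaved"
#' inducible network should look like: basal activity `epsilon` at low
#' inducer, half-saturation at `g = K`, steepness `h`, saturating at 1:
#' \deqn{f_{ref}(g) = \frac{\epsilon + (g/K)^h}{1 + (g/K)^h}}
#'
#' The default (`epsilon = 0`, `K = 0.1`, `h = 2`) places the midpoint
#' at the logarithmic centre of the default grid and demands full
#' OFF-to-ON switching, so a network that switches completely across
#' the induction window with a moderately cooperative response scores a
#' near-zero inducibility penalty. Any headline statistic computed from
#' inducibility penalties should be reported together with the
#' reference configuration used.
#'
#' @param grid Inducer grid (positive values).
#' @param epsilon Basal activity level in `[0, 1)`. The default 0 asks
#'   for full OFF-to-ON switching; note this is basal *activity*, not
#'   the basal production coefficient of the kinetic model.
#' @param K Half-saturation inducer level (> 0).
#' @param h Steepness exponent (> 0).
#' @param values Optional explicit activity values on `grid`,
#'   overriding the Hill form.
#' @return An `"inducibility_curve"` tibble (all points `"ok"`).
#' @examples
#' reference_curve(inducer_grid())
#' @export
reference_curve <- function(grid = inducer_grid(), epsilon = 0,
                            K = 0.1, h = 2, values = NULL) {
  stopifnot(all(grid > 0))
  if (is.null(values)) {
    if (K <= 0 || h <= 0) stop("K and h must be positive", call. = FALSE)
    if (epsilon < 0 || epsilon >= 1) {
      stop("epsilon must lie in [0, 1)", call. = FALSE)
    }
    u <- (grid / K)^h
    values <- (epsilon + u) / (1 + u)
  }
  stopifnot(length(values) == length(grid),
            all(values >= 0), all(values <= 1))
  out <- tibble::tibble(
    g = grid, a_end = NA_real_, i_end = NA_real_, f_end = values,
    status = "ok"
  )
  structure(out, class = c("inducibility_curve", class(out)),
            N = NA_integer_, form = "reference", excluded = FALSE)
}

#' Normalized area between two inducibility curves
#'
#' The penalty metric underlying both compensation and inducibility
#' scoring: the trapezoidal integral of `|f1(g) - f2(g)|` over
#' `log10(g)`, divided by the log-span of the grid. The result is the
#' average absolute activity discrepancy, a dimensionless value in
#' `[0, 1]`; 0 means the curves coincide.
#'
#' @param c1,c2 `"inducibility_curve"` tibbles on the identical grid.
#' @return A single penalty value, or `NA` if either curve contains a
#'   point flagged `"numerical_problem"`.
#' @examples
#' r1 <- reference_curve(inducer_grid(), epsilon = 0)
#' r2 <- reference_curve(inducer_grid(), epsilon = 0.3)
#' normalized_area_between(r1, r2)
#' @export
normalized_area_between <- function(c1, c2) {
  stopifnot(inherits(c1, "inducibility_curve"),
            inherits(c2, "inducibility_curve"))
  if (length(c1$g) != length(c2$g) ||
      any(abs(c1$g - c2$g) > 1e-12 * pmax(c1$g, 1))) {
    stop("curves are not on the same inducer grid", call. = FALSE)
  }
  if (length(c1$g) < 2L) stop("grid must have at least 2 points", call. = FALSE)
  if (any(c1$status != "ok") || any(c2$status != "ok")) return(NA_real_)
  x <- log10(c1$g)
  d <- abs(c1$f_end - c2$f_end)
  area <- sum(diff(x) * (utils::head(d, -1) + utils::tail(d, -1)) / 2)
  area / (x[length(x)] - x[1])
}

#' Area between two inducibility curves on the log-inducer axis
#'
#' The penalty scale used throughout the sweep analyses: the
#' trapezoidal integral of `|f1(g) - f2(g)|` over `log10(g)`, *not*
#' divided by the log-span. On the default two-decade grid a complete
#' factor-of-two shift of a full OFF-to-ON transition scores about
#' 0.30, and curves differing by a constant `d` score `d * span`. See
#' [normalized_area_between()] for the span-normalized variant.
#'
#' @inheritParams normalized_area_between
#' @return The unnormalized area, in `[0, span]`.
#' @export
curve_area_between <- function(c1, c2) {
  span <- log10(c1$g[length(c1$g)]) - log10(c1$g[1])
  span * normalized_area_between(c1, c2)
}

#' Compensation and inducibility penalties of a network
#'
#' Score one network from its single-copy and double-copy inducibility
#' curves. The compensation penalty is the area (on the log10 inducer
#' axis, see [curve_area_between()]) between the `N = 1` and `N = 2`
#' curves (0 = perfect dosage compensation); the inducibility penalty
#' is the area between the `N = 1` curve and a reference curve (large
#' values mean always-OFF or always-ON, non-regulatory behaviour).
#'
#' @param curve_n1,curve_n2 Inducibility curves at copy number 1 and 2.
#' @param reference Reference curve on the same grid; defaults to
#'   [reference_curve()] on the grid of `curve_n1`.
#' @return A one-row tibble: `compensation_penalty`,
#'   `inducibility_penalty`, `excluded`.
#' @export
penalty_scores <- function(curve_n1, curve_n2,
                           reference = reference_curve(curve_n1$g)) {
  comp <- curve_area_between(curve_n1, curve_n2)
  induc <- curve_area_between(curve_n1, reference)
  tibble::tibble(
    compensation_penalty = comp,
    inducibility_penalty = induc,
    excluded = is.na(comp) || is.na(induc)
  )
}

#' Classify a network from its penalty scores
#'
#' Four-way classification against penalty thresholds: a network is
#' compensated when its compensation penalty is at most
#' `comp_threshold` and inducible when its inducibility penalty is at
#' most `induc_threshold`.
#'
#' @param scores A tibble from [penalty_scores()] (or any data frame
#'   with `compensation_penalty` and `inducibility_penalty` columns).
#' @param comp_threshold,induc_threshold Penalty thresholds.
#' @return Character vector with levels `"compensated_inducible"`,
#'   `"compensated_not_inducible"`, `"inducible_not_compensated"`,
#'   `"neither"`.
#' @export
classify_network <- function(scores, comp_threshold = 0.10,
                             induc_threshold = 0.10) {
  if (any(scores$excluded %||% FALSE)) {
    stop("cannot classify excluded networks", call. = FALSE)
  }
  comp <- scores$compensation_penalty <= comp_threshold
  induc <- scores$inducibility_penalty <= induc_threshold
  dplyr::case_when(
    comp & induc ~ "compensated_inducible",
    comp & !induc ~ "compensated_not_inducible",
    !comp & induc ~ "inducible_not_compensated",
    .default = "neither"
  )
}
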