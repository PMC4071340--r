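#' Monte-Carlo sweep configuration
#'
#' Assemble the configuration for a parameter sweep over a topology.
#' The defaults reproduce the canonical study design: maximal
#' production rates in \{300, 1500, 7500\}/hour and half-lives in
#' \{5, 30, 120, Inf\} minutes for both proteins (144 kinetic
#' combinations), `S_a` log-uniform on `[1e-3, 1e3]`, `S_i` log-uniform
#' on `[1e-4, 1e2]`, `alpha` and `beta` uniform on `[0.2, 5]`, dilution
#' rate 0.46/hour, basal coefficients 0.20, and the 81-point
#' logarithmic inducer grid.
#'
#' @param form Topology form tag.
#' @param theta_values Production-rate levels (proteins/hour), used for
#'   both proteins.
#' @param half_life_values Half-life levels (minutes, `Inf` = stable),
#'   used for both proteins.
#' @param n_samples_per_combination Topology-parameter draws per
#'   kinetic combination.
#' @param S_a_range,S_i_range Log-uniform sampling ranges.
#' @param alpha_range,beta_range Uniform sampling ranges.
#' @param constrained_range Optional length-2 override range for the
#'   topology's constrained stoichiometry parameter (`beta` for form B,
#'   `alpha` for form C), used by sufficiency sampling.
#' @param gamma_0 Dilution rate constant (1/hour).
#' @param lambda Basal production coefficient for both proteins.
#' @param grid Inducer grid.
#' @param seed Integer seed governing all sampling.
#' @param comp_threshold,induc_threshold Classification thresholds.
#' @param reference Reference-curve configuration: a list with
#'   `epsilon`, `K`, `h` (see [reference_curve()]).
#' @param literal_basal Passed to [basal_state()]. The sweep default
#'   `TRUE` starts every integration from the single-copy basal formula
#'   regardless of `N` — the convention of the canonical study design;
#'   set `FALSE` to start the `N`-copy network at its own basal fixed
#'   point. The choice matters for bistable draws, where the initial
#'   condition selects the attractor basin.
#' @return A list of class `"sweep_config"`.
#' @export
sweep_config <- function(form = "C_seq_inhibitor",
                         theta_values = c(300, 1500, 7500),
                         half_life_values = c(5, 30, 120, Inf),
                         n_samples_per_combination = 10000,
                         S_a_range = c(1e-3, 1e3),
                         S_i_range = c(1e-4, 1e2),
                         alpha_range = c(0.2, 5),
                         beta_range = c(0.2, 5),
                         constrained_range = NULL,
                         gamma_0 = 0.46, lambda = 0.20,
                         grid = inducer_grid(), seed = 1L,
                         comp_threshold = 0.10, induc_threshold = 0.10,
                         reference = list(epsilon = 0, K = 0.1, h = 2),
                         literal_basal = TRUE) {
  check_form(form)
  check_range <- function(r, nm) {
    if (length(r) != 2L || !all(is.finite(r)) || r[1] > r[2]) {
      stop("`", nm, "` must be a valid (lo <= hi) range", call. = FALSE)
    }
  }
  check_range(S_a_range, "S_a_range"); check_range(S_i_range, "S_i_range")
  check_range(alpha_range, "alpha_range"); check_range(beta_range, "beta_range")
  if (!is.null(constrained_range)) check_range(constrained_range, "constrained_range")
  if (length(theta_values) < 1L || length(half_life_values) < 1L) {
    stop("theta_values and half_life_values must be nonempty", call. = FALSE)
  }
  structure(list(
    form = form, theta_values = theta_values,
    half_life_values = half_life_values,
    n_samples_per_combination = n_samples_per_combination,
    S_a_range = S_a_range, S_i_range = S_i_range,
    alpha_range = alpha_range, beta_range = beta_range,
    constrained_range = constrained_range,
    gamma_0 = gamma_0, lambda = lambda, grid = grid,
    seed = as.integer(seed),
    comp_threshold = comp_threshold, induc_threshold = induc_threshold,
    reference = reference, literal_basal = literal_basal
  ), class = "sweep_config")
}

#' The constrained stoichiometry parameter of a topology
#'
#' For the sequestration topologies the parameter whose value must sit
#' near 1 (1:1 stoichiometry) for dosage compensation is the exponent
#' on the sequestered side: `beta` for form B (inhibitor sequesters
#' activator) and `alpha` for form C (activator sequesters inhibitor).
#'
#' @param form Topology form tag.
#' @return `"alpha"` or `"beta"`.
#' @export
constrained_parameter <- function(form) {
  check_form(form)
  switch(form,
    B_seq_activator = "beta",
    C_seq_inhibitor = "alpha",
    stop("form `", form, "` has no constrained stoichiometry parameter",
         call. = FALSE)
  )
}

#' Enumerate the kinetic parameter combinations of a sweep
#'
#' Cartesian product of activator/inhibitor production rates and
#' half-lives, in a deterministic order (inhibitor half-life varies
#' fastest). With the default levels this yields
#' 3 x 3 x 4 x 4 = 144 combinations.
#'
#' @param cfg A [sweep_config()].
#' @return A tibble with columns `combo_id`, `theta_a`, `theta_i`,
#'   `t_half_a`, `t_half_i`.
#' @export
enumerate_kinetic_combinations <- function(cfg) {
  stopifnot(inherits(cfg, "sweep_config"))
  out <- tidyr::expand_grid(
    theta_a = cfg$theta_values, theta_i = cfg$theta_values,
    t_half_a = cfg$half_life_values, t_half_i = cfg$half_life_values
  )
  dplyr::mutate(out, combo_id = dplyr::row_number(), .before = 1)
}

# evaluate a seed-preserving expression: callers' RNG state is untouched
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Sample topology interaction parameters
#'
#' Draw `n` parameter sets: scales of action log-uniform, stoichiometry
#' exponents uniform, on the configured ranges. Reproducible from the
#' seed.
#'
#' @param n Number of draws.
#' @param cfg A [sweep_config()] supplying the ranges (and the
#'   constrained-range override, if set).
#' @param seed Integer seed; defaults to the config seed.
#' @return A tibble with columns `S_a`, `S_i`, `alpha`, `beta`.
#' @export
sample_topology_params <- function(n, cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sweep_config"), n >= 0)
  if (n == 0) {
    return(tibble::tibble(S_a = numeric(), S_i = numeric(),
                          alpha = numeric(), beta = numeric()))
  }
  ar <- cfg$alpha_range; br <- cfg$beta_range
  if (!is.null(cfg$constrained_range)) {
    cp <- constrained_parameter(cfg$form)
    if (cp == "alpha") ar <- cfg$constrained_range else br <- cfg$constrained_range
  }
  with_local_seed(seed, {
    tibble::tibble(
      S_a = 10^stats::runif(n, log10(cfg$S_a_range[1]), log10(cfg$S_a_range[2])),
      S_i = 10^stats::runif(n, log10(cfg$S_i_range[1]), log10(cfg$S_i_range[2])),
      alpha = stats::runif(n, ar[1], ar[2]),
      beta = stats::runif(n, br[1], br[2])
    )
  })
}

# score one network: N=1 and N=2 curves, penalties, repression diagnostic
evaluate_network <- function(form, p, theta_a, theta_i, t_half_a, t_half_i,
                             gamma_0, lambda, grid, ref_curve,
                             literal_basal = FALSE) {
  k1 <- kinetic_params(theta_a = theta_a, theta_i = theta_i,
                       gamma_0 = gamma_0, t_half_a = t_half_a,
                       t_half_i = t_half_i, lambda_a = lambda,
                       lambda_i = lambda, N = 1L)
  k2 <- kinetic_params(theta_a = theta_a, theta_i = theta_i,
                       gamma_0 = gamma_0, t_half_a = t_half_a,
                       t_half_i = t_half_i, lambda_a = lambda,
                       lambda_i = lambda, N = 2L)
  c1 <- inducibility_curve(form, p, k1, grid, literal_basal = literal_basal)
  c2 <- inducibility_curve(form, p, k2, grid, literal_basal = literal_basal)
  s <- penalty_scores(c1, c2, reference = ref_curve)
  s$max_repression <- max_steady_state_repression(form, p, c1)
  s
}

# min over the grid of f(endpoint) / f(endpoint with inhibitor clamped
# to 0) at N = 1; a value of 1 means the inhibitor never represses
max_steady_state_repression <- function(form, p, curve_n1) {
  ok <- curve_n1$status == "ok"
  if (!any(ok)) return(NA_real_)
  f_with <- curve_n1$f_end[ok]
  f_without <- activity(form, p, curve_n1$g[ok], curve_n1$a_end[ok], 0)
  ratio <- ifelse(f_without > 0, f_with / f_without, 1)
  min(pmin(ratio, 1))
}

#' Run a Monte-Carlo sweep over a topology
#'
#' For every kinetic combination, draw topology parameters and score
#' each network: inducibility curves at copy numbers 1 and 2, the
#' compensation and inducibility penalties, the four-way
#' classification, and the maximum steady-state repression diagnostic.
#' Networks whose integration shows numerical problems are kept as
#' excluded rows so the exclusion rate is auditable.
#'
#' Row order is fixed by (combination index, sample index) and the
#' result is fully reproducible from the config seed.
#'
#' @param cfg A [sweep_config()].
#' @param progress Print a progress line per combination.
#' @return A tibble of class `"dosage_sweep"`, one row per network.
#' @export
run_sweep <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "sweep_config"))
  combos <- enumerate_kinetic_combinations(cfg)
  n <- cfg$n_samples_per_combination
  plan <- tidyr::expand_grid(combo_id = combos$combo_id,
                             sample_id = seq_len(n))
  plan <- dplyr::left_join(plan, combos, by = "combo_id")
  params <- sample_topology_params(nrow(plan), cfg)
  finish_sweep(dplyr::bind_cols(plan, params), cfg, progress)
}

#' Sample networks with uniformly drawn kinetic combinations
#'
#' A reduced-cost sweep: draw `n_total` networks, each with its kinetic
#' combination chosen uniformly at random from the enumerated set and
#' its topology parameters sampled per the config (including any
#' constrained-range override). This is the sampler used for
#' desk-scale sufficiency analyses.
#'
#' @param cfg A [sweep_config()].
#' @param n_total Number of networks to draw.
#' @param progress Print progress.
#' @return A `"dosage_sweep"` tibble, one row per network.
#' @export
sample_sweep <- function(cfg, n_total, progress = FALSE) {
  stopifnot(inherits(cfg, "sweep_config"), n_total >= 0)
  combos <- enumerate_kinetic_combinations(cfg)
  idx <- with_local_seed(cfg$seed,
                         sample.int(nrow(combos), n_total, replace = TRUE))
  plan <- dplyr::mutate(combos[idx, ], sample_id = dplyr::row_number(),
                        .after = "combo_id")
  params <- sample_topology_params(n_total, cfg, seed = cfg$seed + 1L)
  finish_sweep(dplyr::bind_cols(plan, params), cfg, progress)
}

empty_sweep <- function(cfg) {
  out <- tibble::tibble(
    form = character(), combo_id = integer(), sample_id = integer(),
    theta_a = numeric(), theta_i = numeric(), t_half_a = numeric(),
    t_half_i = numeric(), S_a = numeric(), S_i = numeric(),
    alpha = numeric(), beta = numeric(),
    compensation_penalty = numeric(), inducibility_penalty = numeric(),
    excluded = logical(), max_repression = numeric(),
    category = character()
  )
  structure(out, class = c("dosage_sweep", class(out)), config = cfg)
}

finish_sweep <- function(plan, cfg, progress = FALSE) {
  if (nrow(plan) == 0L) return(empty_sweep(cfg))
  ref <- reference_curve(cfg$grid, epsilon = cfg$reference$epsilon,
                         K = cfg$reference$K, h = cfg$reference$h)
  scores <- purrr::pmap(
    list(plan$S_a, plan$S_i, plan$alpha, plan$beta,
         plan$theta_a, plan$theta_i, plan$t_half_a, plan$t_half_i,
         seq_len(nrow(plan))),
    function(S_a, S_i, alpha, beta, theta_a, theta_i,
             t_half_a, t_half_i, row) {
      if (progress && row %% 500 == 0) {
        message("  network ", row, "/", nrow(plan))
      }
      p <- topology_params(S_a = S_a, S_i = S_i, alpha = alpha,
                           beta = beta)
      evaluate_network(cfg$form, p, theta_a, theta_i, t_half_a,
                       t_half_i, cfg$gamma_0, cfg$lambda, cfg$grid, ref,
                       literal_basal = cfg$literal_basal %||% FALSE)
    }
  )
  scores <- dplyr::bind_rows(scores)
  out <- dplyr::bind_cols(
    tibble::tibble(form = rep(cfg$form, nrow(plan))), plan, scores
  )
  out$category <- NA_character_
  if (any(!out$excluded)) {
    out$category[!out$excluded] <- classify_network(
      out[!out$excluded, ], cfg$comp_threshold, cfg$induc_threshold
    )
  }
  structure(out, class = c("dosage_sweep", class(out)), config = cfg)
}

#' Sufficiency analysis of compensation conditions
#'
#' Restrict sweep records to networks whose constrained stoichiometry
#' parameter lies in `constrained_param_range` and whose inducibility
#' penalty is at most `induc_threshold`, then report, for each
#' compensation-penalty cut, the fraction of the filtered networks
#' below and above the cut. For form B the summary also carries the
#' weak-inhibitor diagnostic: the distribution of `S_i` and of the
#' maximum steady-state repression among the high-penalty networks.
#'
#' @param records A `"dosage_sweep"` tibble (forms B or C).
#' @param constrained_param_range Range for the constrained parameter.
#' @param induc_threshold Inducibility-penalty filter.
#' @param comp_cuts Compensation-penalty cuts.
#' @return A list of class `"sufficiency_summary"`: `form`,
#'   `n_filtered`, `cuts` (tibble: `cut`, `n_below`, `frac_below`,
#'   `frac_above`), and `high_penalty` (tibble of `S_i`,
#'   `max_repression`, `compensation_penalty` for filtered networks
#'   with compensation penalty above the first cut).
#' @export
sufficiency_analysis <- function(records,
                                 constrained_param_range = c(0.9, 1.1),
                                 induc_threshold = 0.10,
                                 comp_cuts = c(0.10, 0.15)) {
  form <- unique(records$form)
  stopifnot(length(form) == 1L)
  cp <- constrained_parameter(form)
  keep <- !records$excluded &
    records[[cp]] >= constrained_param_range[1] &
    records[[cp]] <= constrained_param_range[2] &
    records$inducibility_penalty <= induc_threshold
  filtered <- records[keep, ]
  if (nrow(filtered) == 0L) {
    stop("no networks pass the sufficiency filter", call. = FALSE)
  }
  cuts <- tibble::tibble(
    cut = comp_cuts,
    n_below = vapply(comp_cuts,
                     function(cc) sum(filtered$compensation_penalty < cc),
                     integer(1))
  )
  cuts$frac_below <- cuts$n_below / nrow(filtered)
  cuts$frac_above <- 1 - cuts$frac_below
  high <- filtered[filtered$compensation_penalty > comp_cuts[1], ,
                   drop = FALSE]
  structure(list(
    form = form, constrained_parameter = cp,
    n_filtered = nrow(filtered), cuts = cuts,
    high_penalty = tibble::tibble(
      S_i = high$S_i,
      max_repression = high$max_repression,
      compensation_penalty = high$compensation_penalty
    ),
    filtered = filtered
  ), class = "sufficiency_summary")
}

#' @export
print.sufficiency_summary <- function(x, ...) {
  cat("Sufficiency analysis (", x$form, "), constrained parameter ",
      x$constrained_parameter, "\n", sep = "")
  cat("Networks passing filter:", x$n_filtered, "\n")
  for (j in seq_len(nrow(x$cuts))) {
    cat(sprintf("  compensation penalty < %.2f: %5.1f%%\n",
                x$cuts$cut[j], 100 * x$cuts$frac_below[j]))
  }
  invisible(x)
}

#' Histogram of the constrained parameter in a sweep region
#'
#' Distribution of the constrained stoichiometry parameter among the
#' networks of a classification region (by default the compensated and
#' inducible networks), together with the penalty-versus-parameter
#' pairs.
#'
#' @param records A `"dosage_sweep"` tibble.
#' @param region Category to restrict to.
#' @param breaks Histogram breaks, passed to [graphics::hist()]
#'   semantics via [base::cut()]; defaults to 0.1-wide bins spanning
#'   the sampled range.
#' @return A list of class `"constrained_histogram"`: `parameter`,
#'   `n`, `bin_edges`, `counts`, `median`, `central_90`, and `pairs`
#'   (tibble of parameter value vs compensation penalty). Empty
#'   regions give `n = 0` with empty counts and an `empty` flag.
#' @export
constrained_parameter_histogram <- function(records,
                                            region = "compensated_inducible",
                                            breaks = seq(0.2, 5, by = 0.1)) {
  form <- unique(records$form)
  stopifnot(length(form) == 1L)
  cp <- constrained_parameter(form)
  sel <- records[!records$excluded & !is.na(records$category) &
                   records$category == region, , drop = FALSE]
  vals <- sel[[cp]]
  if (length(vals) == 0L) {
    return(structure(list(parameter = cp, n = 0L, bin_edges = breaks,
                          counts = integer(length(breaks) - 1L),
                          median = NA_real_, central_90 = c(NA_real_, NA_real_),
                          pairs = tibble::tibble(value = numeric(),
                                                 compensation_penalty = numeric()),
                          empty = TRUE),
                     class = "constrained_histogram"))
  }
  counts <- as.integer(table(cut(vals, breaks = breaks,
                                 include.lowest = TRUE)))
  structure(list(
    parameter = cp, n = length(vals), bin_edges = breaks, counts = counts,
    median = stats::median(vals),
    central_90 = unname(stats::quantile(vals, c(0.05, 0.95))),
    pairs = tibble::tibble(value = vals,
                           compensation_penalty = sel$compensation_penalty),
    empty = FALSE
  ), class = "constrained_histogram")
}

#' Summarise a sweep
#'
#' Broom-style one-row summary of a `"dosage_sweep"` table: counts per
#' category, the exclusion rate, and the configured thresholds.
#'
#' @param x A `"dosage_sweep"` tibble.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.dosage_sweep <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    form = cfg$form,
    n_networks = nrow(x),
    n_excluded = sum(x$excluded),
    exclusion_rate = mean(x$excluded),
    n_compensated_inducible = sum(x$category == "compensated_inducible",
                                  na.rm = TRUE),
    n_compensated_not_inducible = sum(x$category == "compensated_not_inducible",
                                      na.rm = TRUE),
    n_inducible_not_compensated = sum(x$category == "inducible_not_compensated",
                                      na.rm = TRUE),
    n_neither = sum(x$category == "neither", na.rm = TRUE),
    comp_threshold = cfg$comp_threshold,
    induc_threshold = cfg$induc_threshold
  )
}

#' Tidy a sweep into per-network records
#'
#' @param x A `"dosage_sweep"` tibble.
#' @param ... Unused.
#' @return A plain tibble of per-network records.
#' @export
tidy.dosage_sweep <- function(x, ...) {
  tibble::as_tibble(unclass(x)[setdiff(names(x), character(0))])
}

#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
tidy <- function(x, ...) UseMethod("tidy")
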