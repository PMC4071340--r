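small_cfg <- function(form = "C_seq_inhibitor", ...) {
  sweep_config(
    form = form,
    theta_values = c(300, 1500),
    half_life_values = Inf,
    n_samples_per_combination = 2,
    grid = inducer_grid(seq(0, 80, by = 10)),
    seed = 7L, ...
  )
}

test_that("kinetic combinations enumerate the full Cartesian product", {
  cfg <- sweep_config()
  combos <- enumerate_kinetic_combinations(cfg)
  expect_equal(nrow(combos), 144)
  expect_equal(nrow(dplyr::distinct(combos[-1])), 144)
  expect_equal(sort(unique(combos$theta_a)), c(300, 1500, 7500))
  expect_equal(sort(unique(combos$t_half_i)), c(5, 30, 120, Inf))
  # the planned sweep size is combinations x samples
  expect_equal(nrow(combos) * cfg$n_samples_per_combination, 1440000)
  expect_equal(nrow(enumerate_kinetic_combinations(small_cfg())), 4)
  two <- sweep_config(theta_values = c(300, 1500),
                      half_life_values = c(30, Inf))
  expect_equal(nrow(enumerate_kinetic_combinations(two)), 16)
  one <- sweep_config(theta_values = 300, half_life_values = Inf)
  expect_equal(nrow(enumerate_kinetic_combinations(one)), 1)
  expect_error(sweep_config(theta_values = numeric()), "nonempty")
})

test_that("topology parameters sample within their configured ranges", {
  cfg <- sweep_config(seed = 5L)
  expect_equal(nrow(sample_topology_params(0, cfg)), 0)
  draws <- sample_topology_params(10000, cfg)
  expect_true(all(draws$S_a >= 1e-3 & draws$S_a <= 1e3))
  expect_true(all(draws$S_i >= 1e-4 & draws$S_i <= 1e2))
  expect_true(all(draws$alpha >= 0.2 & draws$alpha <= 5))
  expect_true(all(draws$beta >= 0.2 & draws$beta <= 5))
  # uniform [0.2, 5] mean is 2.6; log-uniform S_a median near 1
  expect_lt(abs(mean(draws$alpha) - 2.6), 0.05)
  expect_lt(abs(stats::median(log10(draws$S_a))), 0.1)
  # reproducible from the seed, and the constrained override restricts
  expect_identical(draws, sample_topology_params(10000, cfg, seed = 5L))
  cfg_c <- sweep_config(form = "C_seq_inhibitor",
                        constrained_range = c(0.9, 1.1))
  dc <- sample_topology_params(500, cfg_c)
  expect_true(all(dc$alpha >= 0.9 & dc$alpha <= 1.1))
  expect_true(any(dc$beta > 1.1)) # beta stays on the full range
  expect_error(sweep_config(S_a_range = c(1, 0.1)), "range")
})

test_that("run_sweep produces one scored row per planned network", {
  cfg <- small_cfg()
  rec <- run_sweep(cfg)
  expect_s3_class(rec, "dosage_sweep")
  expect_equal(nrow(rec), 4 * 2)
  expect_equal(rec$combo_id, rep(1:4, each = 2))
  ok <- !rec$excluded
  expect_true(all(rec$compensation_penalty[ok] >= 0))
  expect_true(all(rec$inducibility_penalty[ok] >= 0))
  expect_true(all(!is.na(rec$category[ok])))
  expect_true(all(is.na(rec$category[!ok])))
  # byte-identical reproducibility from the same config
  expect_identical(tibble::as_tibble(unclass(run_sweep(cfg))),
                   tibble::as_tibble(unclass(rec)))
  g <- glance(rec)
  expect_equal(g$n_networks, 8L)
  expect_equal(g$n_excluded + sum(g[paste0("n_", c(
    "compensated_inducible", "compensated_not_inducible",
    "inducible_not_compensated", "neither"))]), 8L)
})

test_that("empty sweeps and empty sufficiency filters error cleanly", {
  cfg <- small_cfg()
  expect_equal(nrow(sample_sweep(cfg, 0)), 0)
  rec <- run_sweep(cfg)
  expect_error(
    sufficiency_analysis(rec, constrained_param_range = c(99, 100)),
    "no networks")
})

test_that("sufficiency analysis filters and counts correctly", {
  # constructed records: constrained parameter alpha (form C)
  rec <- tibble::tibble(
    form = "C_seq_inhibitor",
    S_a = 1, S_i = c(1e-4, 1, 1, 1, 1, 1),
    alpha = c(1.0, 1.0, 1.05, 0.95, 2.0, 1.0),
    beta = 1,
    compensation_penalty = c(0.20, 0.05, 0.12, 0.01, 0.01, 0.01),
    inducibility_penalty = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.50),
    max_repression = c(0.99, 0.2, 0.3, 0.1, 0.2, 0.2),
    excluded = FALSE, category = "compensated_inducible"
  )
  s <- sufficiency_analysis(rec)
  # row 5 fails the alpha window, row 6 the inducibility filter
  expect_equal(s$n_filtered, 4)
  expect_equal(s$cuts$frac_below[s$cuts$cut == 0.10], 2 / 4)
  expect_equal(s$cuts$frac_below[s$cuts$cut == 0.15], 3 / 4)
  # high-penalty group carries the weak-inhibitor diagnostics
  expect_equal(nrow(s$high_penalty), 2)
  expect_true(1e-4 %in% s$high_penalty$S_i)
  # all-zero penalties put everything below every cut
  rec0 <- dplyr::mutate(rec, compensation_penalty = 0)
  s0 <- sufficiency_analysis(rec0)
  expect_equal(s0$cuts$frac_below, c(1, 1))
})

test_that("constrained-parameter histogram summarises the region", {
  rec <- tibble::tibble(
    form = "B_seq_activator",
    S_a = 1, S_i = 1, alpha = 1,
    beta = c(0.95, 1.0, 1.05, 3.0, 0.97),
    compensation_penalty = c(0.01, 0.02, 0.03, 0.01, 0.02),
    inducibility_penalty = 0.05,
    max_repression = 0.5, excluded = FALSE,
    category = c(rep("compensated_inducible", 3), "neither",
                 "compensated_inducible")
  )
  h <- constrained_parameter_histogram(rec)
  expect_equal(h$parameter, "beta")
  expect_equal(h$n, 4)
  expect_equal(sum(h$counts), 4)
  expect_true(h$median >= 0.9 && h$median <= 1.1)
  expect_equal(nrow(h$pairs), 4)
  # known values land in known bins (0.1-wide bins from 0.2)
  lefts <- h$bin_edges[-length(h$bin_edges)]
  expect_equal(h$counts[which(abs(lefts - 0.9) < 1e-9)], 3L)
  empty <- constrained_parameter_histogram(rec, region = "no_such_region")
  expect_true(empty$empty)
  expect_equal(empty$n, 0L)
})

test_that("sweeps round-trip through CSV", {
  cfg <- small_cfg()
  rec <- run_sweep(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(rec, path)
  back <- read_sweep_csv(path, cfg = cfg)
  expect_equal(back$compensation_penalty, rec$compensation_penalty)
  expect_equal(back$category, rec$category)
  expect_s3_class(back, "dosage_sweep")
})

test_that("tidy and autoplot methods work on sweep results", {
  rec <- run_sweep(small_cfg())
  td <- tidy(rec)
  expect_false(inherits(td, "dosage_sweep"))
  expect_equal(nrow(td), nrow(rec))
  pl <- ggplot2::autoplot(rec)
  expect_s3_class(pl, "ggplot")
  p2 <- ggplot2::autoplot(
    inducibility_curve("CONSTANT_FIXTURE", topology_params(const_level = 0.5),
                       kinetic_params(), inducer_grid(seq(0, 80, 20))))
  expect_s3_class(p2, "ggplot")
})
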