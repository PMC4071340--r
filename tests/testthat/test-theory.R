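# random monostable specs: bounded saturating activity with gain small
# enough that x -> (1+delta) theta1/gamma f(x) is a contraction, so the
# steady state is unique and the finite-difference oracle is well posed
random_spec <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(1:4, 1)
    c0 <- runif(1, 0.2, 0.6)
    cs <- runif(n, -0.3, 0.3)
    theta <- runif(n, 0.5, 3)
    gamma <- runif(1, 2.5, 5)
    delta <- runif(1, -0.2, 0.5)
    f <- function(rho, x) {
      min(max(c0 + sum(cs * x / (1 + x)), 0), 1)
    }
    network_spec(n, f, theta = theta, gamma = gamma, delta = delta)
  })
}

# brute-force df/ddelta: re-solve the steady state at delta and
# delta + h and difference the activity values
finite_difference_sensitivity <- function(spec, h = 1e-6) {
  pick <- function(sp) {
    ss <- steady_states(sp)
    stopifnot(length(ss) >= 1)
    ss[[1]]
  }
  sp2 <- spec; sp2$delta <- spec$delta + h
  f1 <- spec$f(spec$rho, pick(spec))
  f2 <- sp2$f(sp2$rho, pick(sp2))
  (f2 - f1) / h
}

test_that("steady states satisfy the proportionality reduction", {
  for (seed in 1:25) {
    spec <- random_spec(seed)
    states <- steady_states(spec)
    expect_gte(length(states), 1)
    for (x in states) {
      # residual of the scalar fixed-point equation
      resid <- x[1] - (1 + spec$delta) * spec$theta[1] / spec$gamma *
        spec$f(spec$rho, x)
      expect_lt(abs(resid), 1e-6 * max(spec$theta[1] / spec$gamma, 1))
      if (spec$n > 1) {
        expect_equal(x / x[1], spec$theta / spec$theta[1],
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("steady states of known closed-form cases are exact", {
  # constant activity: unique fixed point theta_i c / gamma, scaled by dosage
  spec <- network_spec(3, function(rho, x) 0.4,
                       theta = c(1, 2, 4), gamma = 2, delta = 0.5)
  states <- steady_states(spec)
  expect_length(states, 1)
  expect_equal(states[[1]], 1.5 * c(1, 2, 4) * 0.4 / 2, tolerance = 1e-8)
  # 1-component f = x/(1+x), theta = 2, gamma = 1: roots 0 and 1
  spec1 <- network_spec(1, function(rho, x) x / (1 + x), theta = 2, gamma = 1)
  roots <- vapply(steady_states(spec1), identity, numeric(1))
  expect_equal(sort(roots), c(0, 1), tolerance = 1e-7)
})

test_that("dosage scaling is equivalent to production scaling", {
  spec <- random_spec(99)
  spec_delta <- spec; spec_delta$delta <- 0.7
  spec_theta <- spec
  spec_theta$theta <- spec$theta * 1.7
  spec_theta$delta <- 0
  s1 <- steady_states(spec_delta)
  s2 <- steady_states(spec_theta)
  expect_equal(length(s1), length(s2))
  for (j in seq_along(s1)) expect_equal(s1[[j]], s2[[j]], tolerance = 1e-7)
})

test_that("dosage sensitivity matches the hand-worked 1-component value", {
  spec <- network_spec(1, function(rho, x) x / (1 + x), theta = 2, gamma = 1)
  x_star <- 1
  sens <- dosage_sensitivity(spec, x_star)
  # df/dx = 1/4 at x = 1, f = 1/2: (2 * 1/4 * 1/2) / (1 - 2 * 1/4) = 0.5
  expect_false(sens$singular)
  expect_equal(sens$value, 0.5, tolerance = 1e-6)
})

test_that("dosage sensitivity agrees with the finite-difference oracle", {
  n_checked <- 0
  for (seed in 1:1100) {
    spec <- random_spec(seed)
    states <- steady_states(spec)
    if (length(states) != 1) next # restrict to unambiguous monostable draws
    sens <- dosage_sensitivity(spec, states[[1]])
    if (sens$singular) next
    fd <- finite_difference_sensitivity(spec)
    scale <- max(abs(fd), 1e-8)
    expect_lt(abs(sens$value - fd) / scale, 1e-4)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 1000)
})

test_that("zero weighted sum implies a dosage-insensitive activity", {
  # antisymmetric coefficients with equal theta make the weighted sum
  # vanish at the symmetric steady state
  f <- function(rho, x) {
    min(max(0.5 + 0.2 * (x[1] / (1 + x[1]) - x[2] / (1 + x[2])), 0), 1)
  }
  spec <- network_spec(2, f, theta = c(1, 1), gamma = 2)
  states <- steady_states(spec)
  expect_length(states, 1)
  sens <- dosage_sensitivity(spec, states[[1]])
  expect_lt(abs(sens$weighted_sum), 1e-8)
  fd <- finite_difference_sensitivity(spec)
  expect_lt(abs(fd), 1e-6)
})

test_that("necessary-condition verdicts follow the sign structure", {
  const_spec <- network_spec(2, function(rho, x) 0.3, theta = c(1, 1),
                             gamma = 1)
  ncc <- necessary_condition_check(const_spec, c(0.3, 0.3))
  expect_match(ncc$verdict, "degenerate")

  pos_spec <- network_spec(
    2, function(rho, x) min(max(0.1 + 0.2 * sum(x / (1 + x)), 0), 1),
    theta = c(1, 2), gamma = 3)
  st <- steady_states(pos_spec)[[1]]
  ncc <- necessary_condition_check(pos_spec, st)
  expect_match(ncc$verdict, "impossible")

  # two-component sequestration topology at an interior steady state:
  # activator partial positive, inhibitor partial negative
  p <- topology_params(S_a = 0.01, S_i = 0.01, alpha = 1, beta = 1)
  f <- function(rho, x) activity("C_seq_inhibitor", p, rho, x[1], x[2])
  mixed_spec <- network_spec(2, f, theta = c(100, 100), gamma = 0.46,
                             rho = 0.5)
  st <- steady_states(mixed_spec)[[1]]
  ncc <- necessary_condition_check(mixed_spec, st)
  expect_match(ncc$verdict, "possible")
  expect_true(any(ncc$signs > 0) && any(ncc$signs < 0))
})
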