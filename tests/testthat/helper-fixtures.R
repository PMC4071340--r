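# shared helpers: random parameter draws under a fixed seed

random_topology_params <- function(n, seed = 1L) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(j) {
      topology_params(
        S_a = 10^stats::runif(1, -3, 3),
        S_i = 10^stats::runif(1, -4, 2),
        alpha = stats::runif(1, 0.2, 5),
        beta = stats::runif(1, 0.2, 5)
      )
    })
  })
}

# central-difference gradient oracle for the activity functions
numeric_gradient <- function(form, p, g, a, i, rel = 1e-6) {
  step <- function(x) rel * max(abs(x), 1e-3)
  ha <- step(a); hi <- step(i)
  dfda <- (activity(form, p, g, a + ha, i) -
             activity(form, p, g, max(a - ha, 0), i)) /
    (a + ha - max(a - ha, 0))
  dfdi <- (activity(form, p, g, a, i + hi) -
             activity(form, p, g, a, max(i - hi, 0))) /
    (i + hi - max(i - hi, 0))
  list(dfda = dfda, dfdi = dfdi)
}

# algebraic fixed-point oracle for the induction endpoint: solves
# f = activity(g, A h(f), I h(f)) with h(f) = lambda + (1 - lambda) f
# by dense scan + uniroot, returning the root with the smallest f
# (the branch continuously connected to the basal state)
fixed_point_endpoint <- function(form, p, k, g) {
  A <- k$N * k$theta_a / (k$gamma_0 + k$gamma_a)
  I <- k$N * k$theta_i / (k$gamma_0 + k$gamma_i)
  h <- function(f, lambda) lambda * (1 - f) + f
  resid <- function(f) {
    f - activity(form, p, g, A * h(f, k$lambda_a), I * h(f, k$lambda_i))
  }
  fs <- seq(0, 1, length.out = 2001)
  rs <- vapply(fs, resid, numeric(1))
  for (j in seq_len(length(fs) - 1)) {
    if (rs[j] == 0) return(fs[j])
    if (rs[j] * rs[j + 1] < 0) {
      return(stats::uniroot(resid, c(fs[j], fs[j + 1]), tol = 1e-12)$root)
    }
  }
  if (abs(rs[length(fs)]) < 1e-9) return(1)
  NA_real_
}
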