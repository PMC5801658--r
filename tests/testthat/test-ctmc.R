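test_that("propensities match the printed rate list", {
  p <- default_params()
  # at the empty state only the two influxes fire
  q0 <- propensities(p, rep(0, 7))
  r <- count_rates(p)
  expect_equal(unname(q0[c(4, 10)]),
               unname(r[c("lambda_in", "lambda_r")]))
  expect_true(all(q0[-c(4, 10)] == 0))
  # infection propensity at the reference state, against a hand evaluation
  n <- c(18000, 2000, 7200, 6300, 0, 0, 0)
  q <- propensities(p, n)
  expect_equal(unname(q[3]), (p$beta_t / p$Omega) * 18000 * 2000)
  # full vector against an independent transcription, random states
  set.seed(21)
  for (k in 1:20) {
    pk <- rand_params()
    nk <- round(abs(rnorm(7, 0, 500)))
    expect_equal(unname(propensities(pk, nk)), ref_propensities(pk, nk))
  }
  expect_error(propensities(p, c(-1, 0, 0, 0, 0, 0, 0)), "negative")
})

test_that("drift identity: propensity-weighted stoichiometry is the ODE", {
  S <- reaction_table()$stoich
  set.seed(22)
  for (k in 1:30) {
    pk <- rand_params()
    nk <- round(abs(rnorm(7, 0, 300)))
    q <- propensities(pk, nk)
    expect_identical(unname(drop(S %*% q)), unname(count_rhs(pk, nk)))
  }
})

test_that("diffusion identity: second moment of jumps equals the printed Sigma", {
  S <- reaction_table()$stoich
  set.seed(23)
  for (k in 1:30) {
    pk <- rand_params()
    nk <- abs(rnorm(7, 0, 300))
    q <- propensities(pk, nk, check = FALSE)
    direct <- matrix(0, 7, 7)
    for (j in 1:17) direct <- direct + q[j] * tcrossprod(S[, j])
    expect_equal(direct, unname(drift_diffusion(pk, nk)$Sigma),
                 tolerance = 1e-13)
  }
})

test_that("every reaction keeps the chain in the nonnegative orthant", {
  S <- reaction_table()$stoich
  p <- default_params()
  # any propensity with a -1 entry must vanish when that compartment is 0
  for (j in 1:17) {
    neg <- which(S[, j] < 0)
    if (!length(neg)) next
    n <- rep(5, 7); n[neg] <- 0
    expect_equal(unname(propensities(p, n)[j]), 0)
  }
})

test_that("SSA is reproducible and structurally nonnegative", {
  p <- update_params(default_params(), Omega = 20)
  n0 <- round(20 * ic_infection)
  t1 <- simulate_ssa(p, n0, 1, seed = 7, record = "events",
                     max_events = 20000)
  t2 <- simulate_ssa(p, n0, 1, seed = 7, record = "events",
                     max_events = 20000)
  expect_identical(t1$times, t2$times)
  expect_identical(t1$states, t2$states)
  expect_gte(min(t1$states), 0)
  # successive states differ by exactly one reaction stoichiometry
  S <- reaction_table()$stoich
  i <- nrow(t1$states)
  dif <- t1$states[2:i, , drop = FALSE] - t1$states[1:(i - 1), , drop = FALSE]
  expect_true(all(dif == t(S[, t1$reactions[-1]])))
  expect_error(simulate_ssa(p, c(-1, 0, 0, 0, 0, 0, 0), 1), "nonnegative")
})

test_that("the empty state is absorbing without influx", {
  p <- default_params(lambda_in_t = 0, lambda_r_t = 0)
  tr <- simulate_ssa(p, rep(0, 7), 5, seed = 1)
  expect_true(all(tr$states == 0))
})

test_that("pure-death chain reproduces the analytic extinction time", {
  # only IL-2 decay is active: mean extinction from k units is sum 1/(d_i j)
  p <- default_params(lambda_in_t = 0, lambda_r_t = 0)
  k0 <- 15
  n_runs <- 2000
  ext <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    tr <- simulate_ssa(p, c(0, 0, 0, 0, 0, 0, k0), 100, seed = 100 + i,
                       record = "events", max_events = 100)
    ext[i] <- max(tr$times)
  }
  theo_mean <- sum(1 / (p$d_i * seq_len(k0)))
  theo_sd <- sqrt(sum(1 / (p$d_i * seq_len(k0))^2))
  se <- theo_sd / sqrt(n_runs)
  expect_lt(abs(mean(ext) - theo_mean), 3 * se)
})

test_that("SSA ensemble means track the deterministic model", {
  p <- update_params(default_params(), Omega = 50)
  n0 <- round(50 * ic_infection)
  cps <- seq(0.4, 2, by = 0.4)
  ens <- ensemble_ssa(p, n0, 2, n_runs = 120, base_seed = 5,
                      checkpoints = cps)
  ode <- integrate_ode(p, ic_infection, c(0, cps))
  for (k in seq_along(cps)) {
    i <- which(ens$times == cps[k])
    se <- sqrt(pmax(ens$var[i, ], 1e-12) / ens$n_runs)
    dev <- abs(ens$mean[i, ] - 50 * ode$states[k + 1, ])
    expect_true(all(dev <= 3 * se + 3))   # +3 counts absorbs O(1) bias at tiny Omega
  }
})

test_that("ensemble summaries are consistent with single runs", {
  p <- update_params(default_params(), Omega = 20)
  n0 <- round(20 * ic_infection)
  ens <- ensemble_ssa(p, n0, 1, n_runs = 1, base_seed = 42,
                      checkpoints = c(0.5, 1))
  single <- simulate_ssa(p, n0, 1, seed = 42, record = "grid",
                         times = c(0, 0.5, 1))
  expect_equal(unname(ens$mean), unname(single$states))
})
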