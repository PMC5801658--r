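test_that("the block factor satisfies H H' = Sigma everywhere", {
  set.seed(31)
  worst <- 0
  for (k in 1:1000) {
    pk <- if (k %% 50 == 1) rand_params() else pk
    y <- abs(rnorm(7, 0, 1000))
    dd <- drift_diffusion(pk, y)
    err <- max(abs(tcrossprod(dd$H) - dd$Sigma))
    worst <- max(worst, err / max(dd$Sigma))
  }
  expect_lt(worst, 1e-12)
})

test_that("the SDE drift is exactly the deterministic right-hand side", {
  set.seed(32)
  for (k in 1:20) {
    pk <- rand_params()
    y <- abs(rnorm(7, 0, 500))
    expect_identical(unname(drift_diffusion(pk, y)$mu),
                     unname(count_rhs(pk, y)))
  }
  # without influx, the empty state carries no drift and no noise
  p0 <- default_params(lambda_in_t = 0, lambda_r_t = 0)
  dd <- drift_diffusion(p0, rep(0, 7))
  expect_true(all(dd$mu == 0) && all(dd$Sigma == 0) && all(dd$H == 0))
})

test_that("noise-free Euler-Maruyama converges to the ODE at first order", {
  p <- bistable_params()
  y0 <- p$Omega * ic_infection
  t_out <- c(0, 2)
  ref <- p$Omega * integrate_ode(p, ic_infection, seq(0, 2, length.out = 5),
                                 atol = 1e-12, rtol = 1e-10)$states[5, ]
  e <- sapply(c(4e-3, 2e-3, 1e-3), function(dt) {
    tr <- simulate_em(p, y0, 2, dt = dt, seed = 1, times = t_out,
                      noise_scale = 0)
    max(abs(tr$states[2, ] - ref) / pmax(1, abs(ref)))
  })
  # halving dt roughly halves the endpoint error (explicit Euler)
  expect_gt(e[1] / e[2], 1.5)
  expect_gt(e[2] / e[3], 1.5)
})

test_that("linear birth-death reduction matches exact stationary moments", {
  # only the naive T-cell compartment is active: influx lambda, death d_in;
  # stationary law has mean and variance both lambda/d_in (Poisson limit)
  p <- imm_params(lambda_in_t = 5, d_in = 1, alpha_t = 0, lambda_r_t = 0,
                  sigma1 = 0, sigma2 = 0, Omega = 1)
  mstat <- p$lambda_in_t / p$d_in
  n_runs <- 400
  ends <- matrix(NA_real_, n_runs, 2)
  for (i in seq_len(n_runs)) {
    tr <- simulate_em(p, c(0, 0, mstat, 0, 0, 0, 0), 30, dt = 5e-3,
                      seed = 300 + i, times = c(0, 25, 30))
    ends[i, ] <- tr$states[2:3, 3]
  }
  x <- as.vector(ends[, 2])
  se_mean <- sd(x) / sqrt(n_runs)
  expect_lt(abs(mean(x) - mstat), 3 * se_mean)
  se_var <- var(x) * sqrt(2 / (n_runs - 1))
  expect_lt(abs(var(x) - mstat), 3 * se_var + 0.05 * mstat)
})

test_that("Euler-Maruyama is reproducible and clamps at zero", {
  p <- update_params(default_params(), Omega = 50)
  y0 <- 50 * ic_infection
  a <- simulate_em(p, y0, 2, dt = 2e-3, seed = 9)
  b <- simulate_em(p, y0, 2, dt = 2e-3, seed = 9)
  expect_identical(a$states, b$states)
  expect_gte(min(a$states), 0)
  c2 <- simulate_em(p, y0, 2, dt = 2e-3, seed = 10)
  expect_false(identical(a$states, c2$states))
  expect_error(simulate_em(p, -y0, 1), "nonnegative")
  expect_error(simulate_em(p, y0, 1, dt = 0), "dt")
})

test_that("a one-run ensemble equals a single run with the derived seed", {
  p <- update_params(default_params(), Omega = 50)
  y0 <- 50 * ic_infection
  ens <- ensemble_em(p, y0, 1, dt = 2e-3, n_runs = 1, base_seed = 77,
                     checkpoints = c(0.5, 1))
  single <- simulate_em(p, y0, 1, dt = 2e-3, seed = 77,
                        times = c(0, 0.5, 1))
  expect_equal(unname(ens$mean), unname(single$states))
})

test_that("SDE ensembles agree with exact simulation at moderate system size", {
  p <- update_params(default_params(), Omega = 100)
  n0 <- round(100 * ic_infection)
  cps <- seq(0.5, 2.5, by = 0.5)
  ssa <- ensemble_ssa(p, n0, 2.5, n_runs = 150, base_seed = 1,
                      checkpoints = cps)
  em <- ensemble_em(p, n0, 2.5, dt = 1e-3, n_runs = 150, base_seed = 5000,
                    checkpoints = cps)
  for (tk in cps) {
    i <- which(ssa$times == tk)
    se <- sqrt(ssa$var[i, ] / ssa$n_runs + em$var[i, ] / em$n_runs)
    dev <- abs(ssa$mean[i, ] - em$mean[i, ])
    expect_true(all(dev <= 3 * pmax(se, 1e-6) + 1))
  }
})
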