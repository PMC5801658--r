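test_that("macroscopic vector field matches an independent transcription", {
  p <- default_params()
  # reference initial condition of the simulation studies
  expect_equal(unname(scaled_rhs(p, ic_infection)),
               ref_scaled_rhs(p, ic_infection))
  # random parameter sets and states, including boundary states
  set.seed(11)
  for (k in 1:25) {
    pk <- rand_params()
    x <- rand_state()
    if (k %% 3 == 0) x[sample(7, 2)] <- 0
    expect_equal(unname(scaled_rhs(pk, x)), ref_scaled_rhs(pk, x))
  }
  # at the origin only the two influxes survive
  expect_equal(unname(scaled_rhs(p, rep(0, 7))),
               c(0, 0, p$lambda_in_t, p$lambda_r_t, 0, 0, 0))
  expect_error(scaled_rhs(p, c(1, NA, 1, 1, 1, 1, 1)), "non-finite")
})

test_that("count-form and scaled form are the same model", {
  set.seed(12)
  for (k in 1:20) {
    pk <- rand_params()
    x <- rand_state()
    expect_equal(unname(count_rhs(pk, pk$Omega * x)),
                 pk$Omega * unname(scaled_rhs(pk, x)),
                 tolerance = 1e-12)
  }
})

test_that("closed-form Jacobian agrees with finite differences", {
  set.seed(13)
  for (k in 1:12) {
    pk <- rand_params()
    x <- rand_state()
    A <- jacobian(pk, x)
    expect_equal(unname(A), num_jacobian(pk, x),
                 tolerance = 1e-6)
  }
})

test_that("Jacobian has the expected structure at boundary states", {
  p <- default_params()
  # at the origin: diagonal of decay rates, no state-dependent couplings
  A0 <- jacobian(p, rep(0, 7))
  expect_equal(unname(diag(A0)),
               c(p$b1 - p$d1, -p$d_F, -p$d_in, -p$d_r, -p$d_n, -p$d_a,
                 -p$d_i))
  off <- A0; diag(off) <- 0
  expect_equal(unname(off[7, 5:6]), c(p$sigma1, p$sigma2))
  off[7, 5:6] <- 0
  expect_true(all(off == 0))
  # with x2 = x5 = x6 = x7 = 0, rows 5 and 6 couple only through column 2
  x <- c(3, 0, 5, 2, 0, 0, 0)
  A <- jacobian(p, x)
  for (r in 5:6) {
    expect_equal(unname(A[r, 2]),
                 unname(c(p$p2, 1 - p$p1 - p$p2)[r - 4] * p$alpha_t * x[3]))
    expect_true(all(A[r, -c(r, 2)] == 0))
  }
})

test_that("closed-form steady states have vanishing residuals", {
  p <- default_params()
  ss <- steady_states(p, find_s4 = FALSE)
  expect_true(length(ss) >= 3)
  # disease-free state matches its printed closed form
  expect_equal(unname(ss$S1$x),
               c((p$b1 - p$d1) / (p$d2_t - p$b2_t), 0,
                 p$lambda_in_t / p$d_in, p$lambda_r_t / p$d_r, 0, 0, 0))
  for (s in ss) expect_lt(s$residual, 1e-9)
  # random feasible draws
  set.seed(14)
  for (k in 1:40) {
    sk <- steady_states(rand_params(), find_s4 = FALSE)
    for (s in sk) expect_lt(s$residual, 1e-9)
  }
})

test_that("regulatory T-cell quadratic behaves in the zero-influx limit", {
  p <- default_params(lambda_r_t = 0)
  ss <- steady_states(p, find_s4 = FALSE)
  lab2 <- grep("^S2", names(ss), value = TRUE)
  expect_length(lab2, 1)   # the zero root is dropped, one positive root left
  expect_equal(unname(ss[[lab2]]$x[4]),
               (p$rho3_t * p$d_r - p$rho1_t * p$d_a) /
                 (p$rho1_t * p$delta_t),
               tolerance = 1e-12)
})

test_that("sigma2 = 1 gives bistability of disease-free and autoimmune states", {
  ss <- steady_states(bistable_params(), find_s4 = FALSE)
  expect_identical(ss$S1$stability, "stable")
  expect_identical(ss$S3a$stability, "stable")
  # the autoimmune state is a spiral (complex leading pair): individual
  # stochastic runs can sustain oscillations around it
  lead <- ss$S3a$eigenvalues[which.max(Re(ss$S3a$eigenvalues))]
  expect_gt(abs(Im(lead)), 1e-3)
  # the organ-death branch is transversally unstable here
  expect_identical(ss$S2a$stability, "unstable")
})

test_that("interior chronic-infection state is found when infection can persist", {
  # with a higher infection rate the basic reproduction number exceeds one
  p <- default_params(beta_t = 0.3)
  ss <- steady_states(p)
  expect_true("S4" %in% names(ss))
  expect_true(all(ss$S4$x > 0))
  expect_lt(ss$S4$residual, 1e-9)
  # at the default parameters infection always clears: no interior state
  expect_message(steady_states(default_params()), "no interior")
})

test_that("stability classification uses a symmetric marginal band", {
  expect_identical(stochimm:::stability_class(c(-1, -2e-9)), "stable")
  expect_identical(stochimm:::stability_class(c(-1, 2e-9)), "unstable")
  expect_identical(stochimm:::stability_class(c(-1, 5e-10)), "marginal")
})

test_that("ODE integration is accurate and respects the orthant", {
  p <- bistable_params()
  ss <- steady_states(p, find_s4 = FALSE)
  # a fixed point stays fixed
  tr <- integrate_ode(p, ss$S3a$x, seq(0, 50, length.out = 11))
  expect_lt(max(abs(sweep(tr$states, 2, ss$S3a$x))), 1e-6)
  # halving the tolerances barely moves the endpoint
  t10 <- seq(0, 10, length.out = 21)
  e1 <- integrate_ode(p, ic_infection, t10,
                      atol = 1e-8, rtol = 1e-6)$states[21, ]
  e2 <- integrate_ode(p, ic_infection, t10,
                      atol = 5e-9, rtol = 5e-7)$states[21, ]
  expect_lt(max(abs(e1 - e2) / pmax(1, abs(e2))), 1e-5)
  # trajectories from the orthant stay nonnegative up to solver tolerance
  tr2 <- integrate_ode(p, ic_infection, seq(0, 200, length.out = 101))
  expect_gt(min(tr2$states), -1e-7)
  expect_error(integrate_ode(p, ic_infection, c(0, 0)), "increasing")
})

test_that("small initial infection lies in the autoimmune basin at sigma2 = 1", {
  p <- bistable_params()
  ss <- steady_states(p, find_s4 = FALSE)
  tr <- integrate_ode(p, ic_infection, seq(0, 500, length.out = 26))
  cl <- classify_endpoint(tr$states[26, ], stable_states_of(p))
  expect_identical(cl$label, "S3a")
  expect_lt(cl$distance, 0.05)
  # the transient shows decaying oscillations in autoreactive T cells
  taut <- tr$states[, 6]
  sgn <- diff(sign(diff(taut[5:26])))
  expect_gt(sum(sgn != 0), 2)   # several turning points
})
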