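# shared fixtures and independent oracles

default_params <- function(...) imm_params(...)

# the sigma2 = 1 regime used for the bistability studies
bistable_params <- function(...) imm_params(sigma2 = 1, ...)

ic_infection <- c(18, 2, 7.2, 6.3, 0, 0, 0)       # small initial infection
ic_large_infection <- c(18, 9, 7.2, 6.3, 0, 0, 0) # larger initial infection

# random feasible parameter draw: log-normal jitter around the defaults,
# keeping the structural constraints (b1 > d1, d2 > b2, p1 + p2 <= 1)
rand_params <- function(spread = 0.3) {
  p <- unclass(imm_params())
  jitter <- function(v) v * exp(stats::rnorm(1, 0, spread))
  for (nm in setdiff(names(p), c("p1", "p2", "Omega")))
    p[[nm]] <- jitter(p[[nm]])
  if (p$b1 <= p$d1) p$b1 <- p$d1 * (1 + stats::runif(1, 0.1, 2))
  if (p$d2_t <= p$b2_t) p$d2_t <- p$b2_t * (1 + stats::runif(1, 0.1, 2))
  repeat {
    p$p1 <- stats::runif(1, 0.05, 0.6)
    p$p2 <- stats::runif(1, 0.05, 0.6)
    if (p$p1 + p$p2 < 0.95) break
  }
  do.call(imm_params, p)
}

rand_state <- function(scale = 10) abs(stats::rnorm(7, 0, scale))

# independent second transcription of the macroscopic vector field,
# organised term-by-term (gain minus loss per compartment)
ref_scaled_rhs <- function(p, x) {
  S <- x[1]; F <- x[2]; Tin <- x[3]; Trg <- x[4]
  Tnr <- x[5]; Tat <- x[6]; I <- x[7]
  growth  <- (p$b1 - p$d1) * S - (p$d2_t - p$b2_t) * S^2
  c(growth - p$beta_t * S * F - p$mu_a_t * Tat * S,
    p$beta_t * S * F - p$d_F * F - p$mu_F_t * Tnr * F - p$mu_a_t * Tat * F,
    p$lambda_in_t - p$d_in * Tin - p$alpha_t * Tin * F,
    p$lambda_r_t - p$d_r * Trg + p$p1 * p$alpha_t * Tin * F +
      p$rho1_t * I * Trg,
    p$p2 * p$alpha_t * Tin * F - p$d_n * Tnr + p$rho2_t * I * Tnr,
    (1 - p$p1 - p$p2) * p$alpha_t * Tin * F - p$d_a * Tat -
      p$delta_t * Trg * Tat + p$rho3_t * I * Tat,
    p$sigma1 * Tnr + p$sigma2 * Tat - p$d_i * I)
}

# independent transcription of the 17 propensities in count form
ref_propensities <- function(p, n) {
  O <- p$Omega
  c(p$b1 * n[1] + p$b2_t / O * n[1]^2,
    p$d1 * n[1] + p$d2_t / O * n[1]^2 + p$mu_a_t / O * n[1] * n[6],
    p$beta_t / O * n[1] * n[2],
    p$lambda_in_t * O,
    p$d_in * n[3],
    p$p1 * p$alpha_t / O * n[2] * n[3],
    p$p2 * p$alpha_t / O * n[2] * n[3],
    (1 - p$p1 - p$p2) * p$alpha_t / O * n[2] * n[3],
    (p$d_F + p$mu_F_t / O * n[5] + p$mu_a_t / O * n[6]) * n[2],
    p$lambda_r_t * O + p$rho1_t / O * n[4] * n[7],
    p$d_r * n[4],
    p$rho2_t / O * n[5] * n[7],
    p$d_n * n[5],
    p$rho3_t / O * n[6] * n[7],
    (p$d_a + p$delta_t / O * n[4]) * n[6],
    p$sigma1 * n[5] + p$sigma2 * n[6],
    p$d_i * n[7])
}

# central finite differences of the scaled vector field
num_jacobian <- function(p, x, h_rel = 1e-6) {
  J <- matrix(0, 7, 7)
  for (j in 1:7) {
    h <- h_rel * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (scaled_rhs(p, xp) - scaled_rhs(p, xm)) / (2 * h)
  }
  J
}

# naive Lyapunov oracle by Kronecker vectorisation: A X + X A' + Q = 0
lyap_kron <- function(A, Q) {
  n <- nrow(A)
  matrix(solve(kronecker(diag(n), A) + kronecker(A, diag(n)),
               -as.vector(Q)), n, n)
}

stable_states_of <- function(p) {
  Filter(function(s) s$feasible && s$stability == "stable",
         steady_states(p, find_s4 = FALSE))
}
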