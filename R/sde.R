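#' Drift and diffusion of the chemical-Langevin model
#'
#' Evaluates, at a continuous copy-number state `y`, the drift vector
#' `mu = sum_i P_i s_i` (identical to the count-form deterministic
#' right-hand side), the 7x7 covariance matrix
#' `Sigma = sum_i P_i s_i s_i'`, and the block-diagonal 7x11 diffusion
#' factor `H` with `H H' = Sigma`, where `P_i` are the reaction
#' propensities read on continuous states and `s_i` the stoichiometries.
#' `H` is assembled in its printed block form (a 2x3 block coupling S and F,
#' a 4x7 block for the T-cell compartments, and a 1x1 block for IL-2)
#' rather than as a Cholesky factor, so the factorisation identity is
#' directly testable.
#'
#' Components of `y` are clamped at zero before the propensities are
#' evaluated, so all square-root arguments are nonnegative.
#'
#' @param p an [imm_params()] object.
#' @param y numeric length-7 state (continuous copy numbers).
#' @return A list with `mu` (length 7), `Sigma` (7x7), `H` (7x11) and the
#'   propensity vector `P`.
#' @export
drift_diffusion <- function(p, y) {
  y <- pmax(check_state(y, "y"), 0)
  P <- propensities(p, y, check = FALSE)
  mu <- drift_from_propensities(P)
  Sigma <- sigma_matrix(P)
  H <- h_matrix(P)
  list(mu = mu, Sigma = Sigma, H = H, P = P)
}

# printed 7x7 covariance of state increments per unit time
sigma_matrix <- function(P) {
  S <- matrix(0, 7, 7, dimnames = list(compartments(), compartments()))
  S[1, 1] <- P[1] + P[2] + P[3]
  S[1, 2] <- S[2, 1] <- -P[3]
  S[2, 2] <- P[3] + P[9]
  S[3, 3] <- P[4] + P[5] + P[6] + P[7] + P[8]
  S[3, 4] <- S[4, 3] <- -P[6]
  S[3, 5] <- S[5, 3] <- -P[7]
  S[3, 6] <- S[6, 3] <- -P[8]
  S[4, 4] <- P[6] + P[10] + P[11]
  S[5, 5] <- P[7] + P[12] + P[13]
  S[6, 6] <- P[8] + P[14] + P[15]
  S[7, 7] <- P[16] + P[17]
  S
}

# printed block-diagonal 7x11 factor: H1 (2x3), H2 (4x7), H3 (1x1)
h_matrix <- function(P) {
  H <- matrix(0, 7, 11)
  rownames(H) <- compartments()
  H[1, 1] <- sqrt(P[1] + P[2]); H[1, 2] <- -sqrt(P[3])
  H[2, 2] <- sqrt(P[3]);        H[2, 3] <- sqrt(P[9])
  H[3, 4] <- sqrt(P[4] + P[5])
  H[3, 5] <- -sqrt(P[6]); H[3, 6] <- -sqrt(P[7]); H[3, 7] <- -sqrt(P[8])
  H[4, 5] <- sqrt(P[6]);  H[4, 8] <- sqrt(P[10] + P[11])
  H[5, 6] <- sqrt(P[7]);  H[5, 9] <- sqrt(P[12] + P[13])
  H[6, 7] <- sqrt(P[8]);  H[6, 10] <- sqrt(P[14] + P[15])
  H[7, 11] <- sqrt(P[16] + P[17])
  H
}

#' Euler-Maruyama integration of the Ito SDE
#'
#' Integrates `dY = mu(Y) dt + H(Y) dW` with 11 independent Wiener
#' components by the explicit Euler-Maruyama scheme: Gaussian increments of
#' variance `dt` per step, state clamped at zero after each step.
#' Reproducible under `set.seed(seed)`.
#'
#' @param p an [imm_params()] object.
#' @param y0 initial state (continuous copy numbers, nonnegative).
#' @param t_max horizon (> 0).
#' @param dt step size (default 1e-3 time units; halve it to check
#'   convergence).
#' @param seed integer seed (applied with [set.seed()]).
#' @param times output grid (defaults to 201 equispaced points); states are
#'   recorded at the first step crossing each grid time.
#' @param noise_scale multiplies `H`; `0` reduces the scheme to explicit
#'   Euler for the deterministic model (used for zero-noise limits).
#' @return An `imm_trajectory` (counts scale).
#' @export
simulate_em <- function(p, y0, t_max, dt = 1e-3, seed = NULL, times = NULL,
                        noise_scale = 1) {
  stopifnot(inherits(p, "imm_params"))
  y0 <- check_state(y0, "y0")
  if (any(y0 < 0)) stop("y0 must be nonnegative")
  if (dt <= 0) stop("dt must be positive")
  if (t_max <= 0) stop("t_max must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(times)) times <- seq(0, t_max, length.out = 201)
  out <- cpp_em_grid(y0, count_rates(p), times, dt, noise_scale)
  if (out$blowup >= 0)
    stop(sprintf("EM state became non-finite at t = %.6g; try a smaller dt",
                 out$blowup))
  states <- out$states
  colnames(states) <- compartments()
  new_trajectory(times = times, states = states, scale = "counts",
                 params = p, method = "euler-maruyama", seed = seed,
                 dt = dt)
}

#' Euler-Maruyama ensembles
#'
#' Runs `n_runs` independent SDE trajectories with per-run seeds
#' `base_seed + run - 1`, summarising states at `checkpoints` and keeping
#' the full endpoint sample (needed downstream for histograms, mixture fits
#' and basin classification).
#'
#' @inheritParams ensemble_ssa
#' @param y0 initial state (continuous copy numbers).
#' @param dt Euler-Maruyama step size.
#' @param noise_scale multiplies the diffusion factor (see [simulate_em()]).
#' @return An `imm_ensemble` object (see [ensemble_ssa()]).
#' @export
ensemble_em <- function(p, y0, t_max, dt = 1e-3, n_runs = 1000,
                        base_seed = 1, checkpoints = NULL,
                        keep_samples = FALSE, noise_scale = 1) {
  if (is.null(checkpoints))
    checkpoints <- seq(t_max / 10, t_max, length.out = 10)
  checkpoints <- sort(unique(c(0, checkpoints)))
  run_ensemble(p, y0, t_max, n_runs, base_seed, checkpoints, keep_samples,
               engine = "em", dt = dt, noise_scale = noise_scale)
}
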