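#' The 17-reaction table of the jump process
#'
#' Stoichiometry of the continuous-time Markov chain underlying the model:
#' each of the 17 reactions changes at most two compartments by one unit.
#'
#' @return A list with `stoich`, a 7x17 integer matrix (rows are
#'   compartments, columns reactions), and `description`, a length-17
#'   character vector.
#' @export
reaction_table <- function() {
  S <- matrix(0L, 7, 17,
              dimnames = list(compartments(), paste0("q", 1:17)))
  S[1, 1] <- 1L                      # susceptible birth
  S[1, 2] <- -1L                     # susceptible death / killing
  S[1, 3] <- -1L; S[2, 3] <- 1L      # infection
  S[3, 4] <- 1L                      # naive T influx
  S[3, 5] <- -1L                     # naive T death
  S[3, 6] <- -1L; S[4, 6] <- 1L      # activation -> regulatory
  S[3, 7] <- -1L; S[5, 7] <- 1L      # activation -> normal
  S[3, 8] <- -1L; S[6, 8] <- 1L      # activation -> autoreactive
  S[2, 9] <- -1L                     # infected-cell death / killing
  S[4, 10] <- 1L                     # T_reg influx + IL-2 proliferation
  S[4, 11] <- -1L                    # T_reg death
  S[5, 12] <- 1L                     # T_nor proliferation
  S[5, 13] <- -1L                    # T_nor death
  S[6, 14] <- 1L                     # T_aut proliferation
  S[6, 15] <- -1L                    # T_aut death + suppression
  S[7, 16] <- 1L                     # IL-2 production (pooled)
  S[7, 17] <- -1L                    # IL-2 decay
  list(stoich = S,
       description = c(
         "S birth", "S death + killing by T_aut", "infection of S",
         "T_in influx", "T_in death", "activation to T_reg",
         "activation to T_nor", "activation to T_aut",
         "F death + killing", "T_reg influx/proliferation", "T_reg death",
         "T_nor proliferation", "T_nor death", "T_aut proliferation",
         "T_aut death + suppression", "IL-2 production", "IL-2 decay"))
}

#' Reaction propensities
#'
#' The 17 propensities of the jump process evaluated at a copy-number state
#' `n`, using the count-form rates of [count_rates()]. Every propensity with
#' a negative stoichiometric entry vanishes when that compartment is zero,
#' which makes the nonnegative orthant invariant for the chain.
#'
#' @param p an [imm_params()] object.
#' @param n numeric length-7 copy-number state (nonnegative).
#' @param check validate nonnegativity (disable only in internal hot paths).
#' @return Named numeric length-17 vector of nonnegative rates.
#' @export
propensities <- function(p, n, check = TRUE) {
  n <- check_state(n, "n")
  if (check && any(n < 0)) stop("negative copy numbers")
  r <- count_rates(p)
  q <- c(r["b1"] * n[1] + r["b2"] * n[1]^2,
         r["d1"] * n[1] + r["d2"] * n[1]^2 + r["mu_a"] * n[1] * n[6],
         r["beta"] * n[1] * n[2],
         r["lambda_in"],
         r["d_in"] * n[3],
         r["p1"] * r["alpha"] * n[2] * n[3],
         r["p2"] * r["alpha"] * n[2] * n[3],
         (1 - r["p1"] - r["p2"]) * r["alpha"] * n[2] * n[3],
         (r["d_F"] + r["mu_F"] * n[5] + r["mu_a"] * n[6]) * n[2],
         r["lambda_r"] + r["rho1"] * n[4] * n[7],
         r["d_r"] * n[4],
         r["rho2"] * n[5] * n[7],
         r["d_n"] * n[5],
         r["rho3"] * n[6] * n[7],
         (r["d_a"] + r["delta"] * n[4]) * n[6],
         r["sigma1"] * n[5] + r["sigma2"] * n[6],
         r["d_i"] * n[7])
  names(q) <- paste0("q", 1:17)
  q
}

drift_from_propensities <- function(q) {
  S <- reaction_table()$stoich
  drop(S %*% q)
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Statistically exact sampling of the continuous-time Markov chain defined
#' by [propensities()]: exponential waiting times with the total rate,
#' reaction chosen proportionally to its propensity. Terminates at `t_max`
#' or on extinction of the total rate. The simulation consumes R's RNG
#' stream, so results are reproducible under `set.seed(seed)`.
#'
#' @param p an [imm_params()] object.
#' @param n0 initial copy numbers (nonnegative integers, length 7).
#' @param t_max simulation horizon (> 0).
#' @param seed integer seed (applied with [set.seed()]).
#' @param record `"grid"` records the state at the times in `times`
#'   (default an equispaced grid of 201 points); `"events"` records every
#'   jump (bounded by `max_events`).
#' @param times output grid for `record = "grid"`.
#' @param max_events cap on recorded events for `record = "events"`.
#' @return An `imm_trajectory` (counts scale). For `record = "events"` the
#'   `times`/`states` are the jump chain.
#' @export
simulate_ssa <- function(p, n0, t_max, seed = NULL,
                         record = c("grid", "events"), times = NULL,
                         max_events = 1e7) {
  stopifnot(inherits(p, "imm_params"))
  n0 <- check_state(n0, "n0")
  if (any(n0 < 0) || any(n0 != round(n0)))
    stop("n0 must be nonnegative integers")
  if (t_max <= 0) stop("t_max must be positive")
  record <- match.arg(record)
  if (!is.null(seed)) set.seed(seed)
  r <- count_rates(p)
  if (record == "grid") {
    if (is.null(times)) times <- seq(0, t_max, length.out = 201)
    out <- cpp_ssa_grid(n0, r, times)
    states <- out$states
    colnames(states) <- compartments()
    new_trajectory(times = times, states = states, scale = "counts",
                   params = p, method = "ssa", seed = seed)
  } else {
    out <- cpp_ssa_events(n0, r, t_max, as.integer(max_events))
    states <- out$states
    colnames(states) <- compartments()
    tr <- new_trajectory(times = out$times, states = states,
                         scale = "counts", params = p, method = "ssa",
                         seed = seed)
    tr$reactions <- out$reactions
    tr
  }
}

#' Ensembles of exact simulations
#'
#' Runs `n_runs` independent SSA trajectories with per-run seeds
#' `base_seed + run - 1` and summarises the states at `checkpoints`.
#'
#' @param p an [imm_params()] object.
#' @param n0 initial copy numbers.
#' @param t_max horizon.
#' @param n_runs number of independent runs.
#' @param base_seed integer; run `i` uses seed `base_seed + i - 1`.
#' @param checkpoints times at which states are summarised (defaults to ten
#'   equispaced checkpoints).
#' @param keep_samples keep the full runs x checkpoints x 7 array.
#' @return An `imm_ensemble` object with per-checkpoint `mean` and `var`
#'   (checkpoints x 7), `endpoints` (runs x 7), and optionally `samples`.
#' @export
ensemble_ssa <- function(p, n0, t_max, n_runs, base_seed = 1,
                         checkpoints = NULL, keep_samples = FALSE) {
  if (is.null(checkpoints))
    checkpoints <- seq(t_max / 10, t_max, length.out = 10)
  checkpoints <- sort(unique(c(0, checkpoints)))
  run_ensemble(p, n0, t_max, n_runs, base_seed, checkpoints, keep_samples,
               engine = "ssa")
}

# shared ensemble driver for ssa / em engines
run_ensemble <- function(p, y0, t_max, n_runs, base_seed, checkpoints,
                         keep_samples, engine, dt = 1e-3, noise_scale = 1) {
  K <- length(checkpoints)
  smp <- array(NA_real_, c(n_runs, K, 7))
  for (i in seq_len(n_runs)) {
    tr <- if (engine == "ssa") {
      simulate_ssa(p, y0, t_max, seed = base_seed + i - 1,
                   record = "grid", times = checkpoints)
    } else {
      simulate_em(p, y0, t_max, dt = dt, seed = base_seed + i - 1,
                  times = checkpoints, noise_scale = noise_scale)
    }
    smp[i, , ] <- tr$states
  }
  mn <- apply(smp, c(2, 3), mean)
  vr <- apply(smp, c(2, 3), stats::var)
  dimnames(mn) <- dimnames(vr) <- list(NULL, compartments())
  ends <- smp[, K, , drop = TRUE]
  if (is.null(dim(ends))) ends <- matrix(ends, nrow = n_runs)
  colnames(ends) <- compartments()
  structure(list(times = checkpoints, mean = mn, var = vr,
                 endpoints = ends, n_runs = n_runs, base_seed = base_seed,
                 engine = engine, dt = if (engine == "em") dt else NULL,
                 params = p,
                 samples = if (keep_samples) smp else NULL),
            class = "imm_ensemble")
}

#' @export
print.imm_ensemble <- function(x, ...) {
  cat(sprintf("<imm_ensemble> %s, %d runs, %d checkpoints on [%g, %g]\n",
              x$engine, x$n_runs, length(x$times), min(x$times),
              max(x$times)))
  cat("endpoint means:\n")
  print(signif(colMeans(x$endpoints), 6))
  invisible(x)
}
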