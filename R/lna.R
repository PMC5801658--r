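#' Linear-noise-approximation noise matrix B
#'
#' The 7x7 symmetric noise matrix of the linear Fokker-Planck equation for
#' fluctuations around a macroscopic state `x`. It equals the jump-process
#' covariance [sigma_matrix()] evaluated at `Omega * x` and rescaled by
#' `1/Omega`, and is therefore independent of `Omega`; the closed form is
#' evaluated directly in scaled variables.
#'
#' @param p an [imm_params()] object.
#' @param x scaled state (length 7, nonnegative).
#' @return A 7x7 symmetric positive-semidefinite matrix.
#' @export
noise_matrix_B <- function(p, x) {
  x <- check_state(x)
  if (any(x < 0)) stop("x must be nonnegative")
  B <- matrix(0, 7, 7, dimnames = list(compartments(), compartments()))
  with(p, {
    act <- alpha_t * x[2] * x[3]
    B[1, 1] <<- b1 * x[1] + b2_t * x[1]^2 + d1 * x[1] + d2_t * x[1]^2 +
      beta_t * x[1] * x[2] + mu_a_t * x[1] * x[6]
    B[2, 2] <<- beta_t * x[1] * x[2] + d_F * x[2] + mu_F_t * x[2] * x[5] +
      mu_a_t * x[2] * x[6]
    B[3, 3] <<- lambda_in_t + d_in * x[3] + act
    B[4, 4] <<- lambda_r_t + d_r * x[4] + p1 * act + rho1_t * x[4] * x[7]
    B[5, 5] <<- p2 * act + d_n * x[5] + rho2_t * x[5] * x[7]
    B[6, 6] <<- (1 - p1 - p2) * act + d_a * x[6] + delta_t * x[4] * x[6] +
      rho3_t * x[6] * x[7]
    B[7, 7] <<- sigma1 * x[5] + sigma2 * x[6] + d_i * x[7]
    B[1, 2] <<- B[2, 1] <<- -beta_t * x[1] * x[2]
    B[3, 4] <<- B[4, 3] <<- -p1 * act
    B[3, 5] <<- B[5, 3] <<- -p2 * act
    B[3, 6] <<- B[6, 3] <<- -(1 - p1 - p2) * act
  })
  B
}

#' Bartels-Stewart solver for the continuous Lyapunov equation
#'
#' Solves `A X + X A' + Q = 0` for dense `A` by real Schur decomposition and
#' quasi-triangular back-substitution (blocks of size 1 or 2 handled through
#' small Kronecker systems). Requires that no two eigenvalues of `A` sum to
#' zero; for a Hurwitz-stable `A` and symmetric positive-semidefinite `Q`
#' the solution is the stationary covariance of the associated
#' Ornstein-Uhlenbeck process.
#'
#' @param A square numeric matrix.
#' @param Q square numeric matrix of the same dimension.
#' @return The solution matrix `X`.
#' @export
lyap_solve <- function(A, Q) {
  n <- nrow(A)
  stopifnot(ncol(A) == n, all(dim(Q) == n))
  sch <- Matrix::Schur(Matrix::Matrix(A), vectors = TRUE)
  Tm <- as.matrix(sch@T)
  U <- as.matrix(sch@Q)
  G <- crossprod(U, Q %*% U)       # T Y + Y T' + G = 0
  # block partition of the quasi-triangular T
  bs <- integer(0)
  i <- 1
  while (i <= n) {
    if (i < n && abs(Tm[i + 1, i]) > 0) {
      bs <- c(bs, 2L); i <- i + 2L
    } else {
      bs <- c(bs, 1L); i <- i + 1L
    }
  }
  starts <- cumsum(c(1L, bs))[seq_along(bs)]
  nb <- length(bs)
  idx <- function(k) seq.int(starts[k], length.out = bs[k])
  Y <- matrix(0, n, n)
  for (bi in rev(seq_len(nb))) {
    for (bj in rev(seq_len(nb))) {
      ii <- idx(bi); jj <- idx(bj)
      R <- -G[ii, jj, drop = FALSE]
      if (bi < nb) {
        kk <- seq.int(starts[bi] + bs[bi], n)
        R <- R - Tm[ii, kk, drop = FALSE] %*% Y[kk, jj, drop = FALSE]
      }
      if (bj < nb) {
        ll <- seq.int(starts[bj] + bs[bj], n)
        R <- R - Y[ii, ll, drop = FALSE] %*% t(Tm[jj, ll, drop = FALSE])
      }
      M <- kronecker(diag(bs[bj]), Tm[ii, ii, drop = FALSE]) +
        kronecker(Tm[jj, jj, drop = FALSE], diag(bs[bi]))
      Y[ii, jj] <- matrix(solve(M, as.vector(R)), bs[bi], bs[bj])
    }
  }
  X <- U %*% Y %*% t(U)
  (X + t(X)) / 2
}

#' Stationary fluctuation covariance at a stable steady state
#'
#' Solves the stationary Lyapunov equation of the linear-noise
#' approximation, `A Xi + Xi A' + B = 0`, at a stable steady state `ss`
#' (Jacobian `A`, noise matrix `B`), via the Bartels-Stewart solver.
#' `Xi` is the covariance of the scaled fluctuations and is independent of
#' the system size; the copy-number covariance is `C = Omega * Xi`, so that
#' `C` solves `A C + C A' + Omega B = 0`.
#'
#' @param p an [imm_params()] object.
#' @param ss an `imm_steady_state` (from [steady_states()]); must be
#'   classified strictly stable, otherwise no stationary covariance exists
#'   and an error is raised.
#' @param Omega system size for the count-scale covariance (defaults to
#'   `p$Omega`).
#' @return An `imm_lna` object: list with the steady state, `A`, `B`, `Xi`,
#'   `C`, and `residual = ||A C + C A' + Omega B||_inf / ||Omega B||_inf`.
#' @export
stationary_covariance <- function(p, ss, Omega = p$Omega) {
  stopifnot(inherits(p, "imm_params"), inherits(ss, "imm_steady_state"))
  if (ss$stability != "stable")
    stop("no stationary covariance: steady state ", ss$label, " is ",
         ss$stability)
  A <- jacobian(p, ss$x)
  B <- noise_matrix_B(p, pmax(ss$x, 0))
  Xi <- lyap_solve(A, B)
  dimnames(Xi) <- dimnames(B)
  C <- Omega * Xi
  res <- max(abs(A %*% C + C %*% t(A) + Omega * B)) /
    max(abs(Omega * B))
  structure(list(steady_state = ss, A = A, B = B, Xi = Xi, C = C,
                 Omega = Omega, residual = res),
            class = "imm_lna")
}

#' @export
print.imm_lna <- function(x, ...) {
  cat(sprintf("<imm_lna> fluctuations around %s (Omega = %g, residual %.2e)\n",
              x$steady_state$label, x$Omega, x$residual))
  cat("count-scale standard deviations:\n")
  print(signif(sqrt(pmax(diag(x$C), 0)), 6))
  invisible(x)
}

#' Parameter-plane map of fluctuation variance
#'
#' For every point of a two-parameter grid, recomputes the steady states,
#' locates the target family (by `label_base`, e.g. all `S3` roots), tests
#' deterministic stability, and -- where a stable representative exists --
#' records the count-scale stationary variance `diag(C)[component]` from
#' the Lyapunov equation. Unstable or infeasible cells are masked (`NA`),
#' so the unmasked region traces the deterministic stability region.
#'
#' @param p base [imm_params()] object.
#' @param axis1,axis2 lists `list(name = <parameter>, values = <grid>)`.
#' @param target steady-state family: `"S1"`, `"S2"` or `"S3"`.
#' @param component compartment index 1..7 (4 = regulatory T cells).
#' @return An `imm_variance_map`: data frame with columns `p1`, `p2`,
#'   `stable`, `variance`, plus attributes `axis1`, `axis2`, `target`,
#'   `component`.
#' @export
variance_map <- function(p, axis1, axis2, target = "S3", component = 4) {
  stopifnot(inherits(p, "imm_params"),
            axis1$name %in% names(p), axis2$name %in% names(p),
            component %in% 1:7)
  grid <- expand.grid(p1 = axis1$values, p2 = axis2$values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$stable <- FALSE
  grid$variance <- NA_real_
  for (i in seq_len(nrow(grid))) {
    args <- stats::setNames(list(grid$p1[i], grid$p2[i]),
                            c(axis1$name, axis2$name))
    pi_ <- tryCatch(do.call(update_params, c(list(p), args)),
                    error = function(e) NULL)
    if (is.null(pi_)) next
    sts <- tryCatch(steady_states(pi_, find_s4 = FALSE),
                    error = function(e) list())
    cand <- Filter(function(s)
      identical(s$label_base, target) && s$feasible &&
        s$stability == "stable", sts)
    if (!length(cand)) next
    # the dynamically relevant representative is the stable one; if several
    # roots are stable, take the one with the largest stability margin
    margins <- vapply(cand, function(s) -max(Re(s$eigenvalues)), numeric(1))
    s <- cand[[which.max(margins)]]
    lc <- tryCatch(stationary_covariance(pi_, s), error = function(e) NULL)
    if (is.null(lc)) next
    grid$stable[i] <- TRUE
    grid$variance[i] <- diag(lc$C)[component]
  }
  names(grid)[1:2] <- c(axis1$name, axis2$name)
  structure(grid, class = c("imm_variance_map", "data.frame"),
            axis1 = axis1, axis2 = axis2, target = target,
            component = component)
}

#' Empirical stationary covariance from SDE ensembles
#'
#' Monte-Carlo counterpart of [stationary_covariance()]: simulates
#' Euler-Maruyama trajectories started at the steady state, discards a
#' burn-in (by default five times the slowest relaxation time
#' `1/|max Re eigenvalue|`), optionally keeps only runs whose endpoint is
#' classified at the target attractor, and pools deviations from the
#' empirical mean across runs and retained times.
#'
#' @param p an [imm_params()] object.
#' @param ss the stable `imm_steady_state` to probe.
#' @param t_max horizon; must exceed the burn-in.
#' @param n_runs number of runs.
#' @param dt Euler-Maruyama step.
#' @param base_seed per-run seeds are `base_seed + run - 1`.
#' @param burn_in burn-in time (default `5 / |max Re eig|`).
#' @param sample_every spacing of pooled time points after burn-in.
#' @param attractors optional list of steady states used to filter runs
#'   that escaped to another basin (endpoint classification threshold 0.5);
#'   `NULL` keeps all runs.
#' @return A list with `cov` (7x7 pooled covariance, counts scale), `mean`,
#'   `n_retained`, `n_pooled`, `burn_in`.
#' @export
empirical_covariance <- function(p, ss, t_max, n_runs = 100, dt = 1e-3,
                                 base_seed = 1, burn_in = NULL,
                                 sample_every = 0.5, attractors = NULL) {
  stopifnot(inherits(ss, "imm_steady_state"))
  if (is.null(burn_in))
    burn_in <- 5 / abs(max(Re(ss$eigenvalues)))
  if (t_max <= burn_in)
    stop("t_max must exceed the burn-in (", signif(burn_in, 3), ")")
  times <- seq(burn_in, t_max, by = sample_every)
  y0 <- round(ss$x * p$Omega)
  keep <- matrix(NA_real_, 0, 7)
  n_ret <- 0L
  for (i in seq_len(n_runs)) {
    tr <- simulate_em(p, y0, t_max, dt = dt, seed = base_seed + i - 1,
                      times = times)
    if (!is.null(attractors)) {
      lab <- classify_endpoint(tr$states[nrow(tr$states), ] / p$Omega,
                               attractors, threshold = 0.5)
      if (!identical(lab$label, ss$label)) next
    }
    keep <- rbind(keep, tr$states)
    n_ret <- n_ret + 1L
  }
  if (!n_ret) stop("no runs retained around ", ss$label)
  list(cov = stats::cov(keep), mean = colMeans(keep),
       n_retained = n_ret, n_pooled = nrow(keep), burn_in = burn_in)
}
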