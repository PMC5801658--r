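#' Deterministic right-hand side (macroscopic form)
#'
#' Time derivative of the seven macroscopic concentrations
#' `x = (S, F, T_in, T_reg, T_nor, T_aut, I)` under the scaled model.
#' Components may be probed slightly negative by adaptive solvers; the
#' expression is evaluated as written.
#'
#' @param p an [imm_params()] object.
#' @param x numeric length-7 state (macroscopic units).
#' @return Named numeric length-7 vector `dx/dt`.
#' @export
scaled_rhs <- function(p, x) {
  x <- check_state(x)
  with(p, {
    dx <- c(
      b1 * x[1] + b2_t * x[1]^2 - d1 * x[1] - d2_t * x[1]^2 -
        beta_t * x[1] * x[2] - mu_a_t * x[1] * x[6],
      beta_t * x[1] * x[2] - d_F * x[2] - mu_F_t * x[2] * x[5] -
        mu_a_t * x[2] * x[6],
      lambda_in_t - d_in * x[3] - alpha_t * x[2] * x[3],
      lambda_r_t - d_r * x[4] + p1 * alpha_t * x[2] * x[3] +
        rho1_t * x[4] * x[7],
      p2 * alpha_t * x[2] * x[3] - d_n * x[5] + rho2_t * x[5] * x[7],
      (1 - p1 - p2) * alpha_t * x[2] * x[3] - d_a * x[6] -
        delta_t * x[4] * x[6] + rho3_t * x[6] * x[7],
      sigma1 * x[5] + sigma2 * x[6] - d_i * x[7])
    names(dx) <- compartments()
    dx
  })
}

#' Deterministic right-hand side (copy-number form)
#'
#' The same vector field in copy numbers `n = Omega * x`, using the
#' count-form rates of [count_rates()]. Identical to
#' `Omega * scaled_rhs(p, n / Omega)`.
#'
#' @param p an [imm_params()] object.
#' @param n numeric length-7 state (copy numbers).
#' @return Named numeric length-7 vector `dn/dt`.
#' @export
count_rhs <- function(p, n) {
  n <- check_state(n)
  q <- propensities(p, n, check = FALSE)
  drift_from_propensities(q)
}

#' Jacobian of the macroscopic model
#'
#' Closed-form 7x7 Jacobian of [scaled_rhs()] at `x`.
#'
#' @inheritParams scaled_rhs
#' @return A 7x7 matrix with dimnames the compartment names.
#' @export
jacobian <- function(p, x) {
  x <- check_state(x)
  A <- matrix(0, 7, 7, dimnames = list(compartments(), compartments()))
  with(p, {
    A[1, 1] <<- b1 + 2 * b2_t * x[1] - d1 - 2 * d2_t * x[1] -
      beta_t * x[2] - mu_a_t * x[6]
    A[1, 2] <<- -beta_t * x[1]
    A[1, 6] <<- -mu_a_t * x[1]
    A[2, 1] <<- beta_t * x[2]
    A[2, 2] <<- beta_t * x[1] - d_F - mu_F_t * x[5] - mu_a_t * x[6]
    A[2, 5] <<- -mu_F_t * x[2]
    A[2, 6] <<- -mu_a_t * x[2]
    A[3, 2] <<- -alpha_t * x[3]
    A[3, 3] <<- -d_in - alpha_t * x[2]
    A[4, 2] <<- p1 * alpha_t * x[3]
    A[4, 3] <<- p1 * alpha_t * x[2]
    A[4, 4] <<- rho1_t * x[7] - d_r
    A[4, 7] <<- rho1_t * x[4]
    A[5, 2] <<- p2 * alpha_t * x[3]
    A[5, 3] <<- p2 * alpha_t * x[2]
    A[5, 5] <<- rho2_t * x[7] - d_n
    A[5, 7] <<- rho2_t * x[5]
    A[6, 2] <<- (1 - p1 - p2) * alpha_t * x[3]
    A[6, 3] <<- (1 - p1 - p2) * alpha_t * x[2]
    A[6, 4] <<- -delta_t * x[6]
    A[6, 6] <<- rho3_t * x[7] - d_a - delta_t * x[4]
    A[6, 7] <<- rho3_t * x[6]
    A[7, 5] <<- sigma1
    A[7, 6] <<- sigma2
    A[7, 7] <<- -d_i
  })
  A
}

# stability from eigenvalues with a symmetric tolerance band
stability_class <- function(eigenvalues, tol = 1e-9) {
  m <- max(Re(eigenvalues))
  if (m < -tol) "stable" else if (m > tol) "unstable" else "marginal"
}

new_steady_state <- function(p, label, x, conditions = NULL) {
  x <- check_state(x)
  names(x) <- compartments()
  res <- max(abs(scaled_rhs(p, x))) / max(1, max(abs(x)))
  ev <- eigen(jacobian(p, x), only.values = TRUE)$values
  cls <- stability_class(ev)
  structure(list(label = label, x = x,
                 feasible = all(x >= -1e-12),
                 stable = cls == "stable",
                 stability = cls,
                 eigenvalues = ev,
                 conditions = conditions,
                 residual = res),
            class = "imm_steady_state")
}

#' @export
print.imm_steady_state <- function(x, ...) {
  cat(sprintf("<imm_steady_state> %s: %s, %s (max Re eig %.3g, residual %.2g)\n",
              x$label, if (x$feasible) "feasible" else "infeasible",
              x$stability, max(Re(x$eigenvalues)), x$residual))
  print(signif(x$x, 6))
  if (!is.null(x$conditions)) {
    cat("  printed-condition verdicts:",
        paste(sprintf("%s=%s", names(x$conditions), x$conditions),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# roots of the quadratic for the regulatory T-cell level at S2*/S3*:
#   rho1*delta * z^2 + (rho1*d_a - rho3*d_r) * z + rho3*lambda_r = 0
# solved with the cancellation-free form; returns sorted real positive roots
treg_quadratic_roots <- function(p) {
  a <- p$rho1_t * p$delta_t
  b <- p$rho1_t * p$d_a - p$rho3_t * p$d_r
  cc <- p$rho3_t * p$lambda_r_t
  if (a == 0) {                       # degenerate: linear equation
    if (b == 0) return(numeric(0))
    r <- -cc / b
    return(r[r > 0])
  }
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(numeric(0))
  if (cc == 0) {                      # roots 0 and -b/a
    r <- c(0, -b / a)
  } else {
    q <- -(b + sign(b + (b == 0)) * sqrt(disc)) / 2
    r <- c(q / a, cc / q)
  }
  sort(r[r > 0 & is.finite(r)])
}

# the autoimmune-branch components shared by S2*/S3* for a given root z = x4*
branch_components <- function(p, z) {
  g <- p$d_a + p$delta_t * z
  list(x4 = z,
       x6 = p$d_i * g / (p$rho3_t * p$sigma2),
       x7 = g / p$rho3_t,
       x1_s3 = (p$rho3_t * p$sigma2 * (p$b1 - p$d1) -
                  p$mu_a_t * p$d_i * g) /
         (p$rho3_t * p$sigma2 * (p$d2_t - p$b2_t)))
}

# printed (de-mangled) sufficient stability conditions for S2*/S3*;
# reported as verdicts only -- eigenvalues decide the `stable` flag
branch_conditions <- function(p, z, K) {
  g <- (p$d_a + p$delta_t * z) / p$rho3_t   # = x7*
  q1 <- is.finite(K) && K != 0 &&
    (p$sigma2 * p$mu_a_t) / (p$d_i * K) < g
  q2 <- g < p$d_n / p$rho2_t
  q3 <- (p$delta_t / p$rho1_t) * z^2 > p$lambda_r_t / p$rho3_t
  q4 <- p$rho3_t * p$lambda_r_t^2 + p$rho3_t * p$d_i * p$lambda_r_t * z -
    p$rho3_t * p$d_i * p$d_a * z^2 -
    p$delta_t * (p$rho1_t * p$d_a + p$rho3_t * p$d_i) * z^3 -
    p$rho1_t * p$delta_t^2 * z^4 > 0
  c(killing_bound = isTRUE(q1), tnor_bound = isTRUE(q2),
    suppression_bound = isTRUE(q3), quartic = isTRUE(q4))
}

#' Steady states of the macroscopic model
#'
#' Computes all steady states of the deterministic model:
#' \describe{
#'   \item{S1}{disease-free: `((b1-d1)/(d2_t-b2_t), 0, lambda_in_t/d_in,
#'     lambda_r_t/d_r, 0, 0, 0)`, in closed form.}
#'   \item{S2}{organ-cell death (`S = 0`), one per admissible root of the
#'     regulatory T-cell quadratic; closed form.}
#'   \item{S3}{autoimmune regime (`S > 0`, no infection), one per admissible
#'     root; closed form. Only returned when its first component is
#'     positive (feasibility).}
#'   \item{S4}{chronic infection (all components positive), found by a
#'     damped Newton search from a lattice of starting points; omitted with
#'     a message when no such state exists.}
#' }
#' Each state carries eigenvalues of the closed-form Jacobian, a stability
#' classification (`stable` strictly negative real parts within tolerance
#' `1e-9`, `marginal` within the band), the verdicts of the printed
#' inequality conditions, and the scaled fixed-point residual.
#'
#' When both quadratic roots are admissible the labels are suffixed
#' (`S2a`/`S2b`, `S3a`/`S3b`) with `a` the larger (dynamically relevant)
#' root; plain labels `S2`/`S3` are used when only one root survives.
#' `label_base` distinguishes the family.
#'
#' @param p an [imm_params()] object.
#' @param find_s4 also search for the interior chronic-infection state.
#' @param s4_starts optional matrix of additional Newton starting points
#'   (rows are length-7 scaled states).
#' @return A named list of `imm_steady_state` objects.
#' @export
steady_states <- function(p, find_s4 = TRUE, s4_starts = NULL) {
  stopifnot(inherits(p, "imm_params"))
  out <- list()
  s1 <- c((p$b1 - p$d1) / (p$d2_t - p$b2_t), 0,
          p$lambda_in_t / p$d_in, p$lambda_r_t / p$d_r, 0, 0, 0)
  ss1 <- new_steady_state(p, "S1", s1,
                          conditions = c(printed_dF_gt_beta = p$d_F > p$beta_t,
                                         transversal = p$d_F > p$beta_t * s1[1]))
  ss1$label_base <- "S1"
  out$S1 <- ss1

  roots <- treg_quadratic_roots(p)
  roots <- sort(roots, decreasing = TRUE)   # 'a' = larger root first
  suff <- if (length(roots) > 1) c("a", "b") else ""
  for (i in seq_along(roots)) {
    z <- roots[i]
    bc <- branch_components(p, z)
    if (!is.finite(bc$x6) || !is.finite(bc$x7)) next
    lab2 <- paste0("S2", suff[i])
    s2 <- c(0, 0, p$lambda_in_t / p$d_in, z, 0, bc$x6, bc$x7)
    ss <- new_steady_state(p, lab2, s2, conditions = branch_conditions(p, z, 1))
    ss$label_base <- "S2"
    out[[lab2]] <- ss
    if (is.finite(bc$x1_s3) && bc$x1_s3 > 0) {
      lab3 <- paste0("S3", suff[i])
      s3 <- c(bc$x1_s3, 0, p$lambda_in_t / p$d_in, z, 0, bc$x6, bc$x7)
      K <- (p$beta_t - p$d_F) / (1 + p$beta_t)
      ss <- new_steady_state(p, lab3, s3, conditions = branch_conditions(p, z, K))
      ss$label_base <- "S3"
      out[[lab3]] <- ss
    }
  }

  if (find_s4) {
    s4 <- find_chronic_state(p, out, s4_starts)
    if (!is.null(s4)) {
      ss <- new_steady_state(p, "S4", s4)
      ss$label_base <- "S4"
      out$S4 <- ss
    } else {
      message("steady_states: no interior (chronic-infection) state found")
    }
  }
  out
}

# damped Newton on scaled_rhs; returns the root or NULL
newton_root <- function(p, x0, max_iter = 200, tol = 1e-12) {
  x <- x0
  for (k in seq_len(max_iter)) {
    f <- scaled_rhs(p, x)
    nf <- max(abs(f))
    if (!is.finite(nf)) return(NULL)
    if (nf < tol * max(1, max(abs(x)))) return(x)
    J <- jacobian(p, x)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      xn <- x - lam * step
      fn <- max(abs(scaled_rhs(p, xn)))
      if (is.finite(fn) && fn < nf) break
      lam <- lam / 2
      if (lam < 1e-10) return(NULL)
    }
    x <- xn
  }
  NULL
}

find_chronic_state <- function(p, known, extra_starts = NULL) {
  starts <- list()
  base <- c((p$b1 - p$d1) / (p$d2_t - p$b2_t), 1,
            p$lambda_in_t / p$d_in, p$lambda_r_t / p$d_r, 1, 1, 1)
  for (f in c(0.2, 1, 5)) starts[[length(starts) + 1]] <- base * f
  for (s in known) {
    pert <- s$x
    pert[pert == 0] <- 0.5 * mean(pert[pert > 0])
    starts[[length(starts) + 1]] <- pert
  }
  # midpoint of a short trajectory from a generic infected initial condition
  tr <- tryCatch(integrate_ode(p, base, seq(0, 20, length.out = 5)),
                 error = function(e) NULL)
  if (!is.null(tr)) starts[[length(starts) + 1]] <- tr$states[3, ]
  if (!is.null(extra_starts))
    for (i in seq_len(nrow(extra_starts)))
      starts[[length(starts) + 1]] <- extra_starts[i, ]
  hits <- list()
  for (x0 in starts) {
    r <- newton_root(p, pmax(x0, 1e-6))
    if (is.null(r) || any(r < 1e-8)) next      # interior only
    dup <- any(vapply(hits, function(h)
      max(abs(h - r)) / max(1, max(abs(r))) < 1e-6, logical(1)))
    if (!dup) hits[[length(hits) + 1]] <- r
  }
  if (!length(hits)) return(NULL)
  hits[[1]]
}

#' Integrate the macroscopic model
#'
#' Stiff-capable adaptive integration of [scaled_rhs()] (lsoda) sampled on
#' `times`. States are not constrained to the orthant; the vector field is
#' evaluated as written (invariance of the nonnegative orthant holds up to
#' integration tolerance).
#'
#' @param p an [imm_params()] object.
#' @param x0 initial scaled state (length 7).
#' @param times strictly increasing numeric vector of output times.
#' @param atol,rtol absolute/relative tolerances passed to the integrator.
#' @return An `imm_trajectory` object: list with `times`, `states`
#'   (length(times) x 7 matrix), `scale = "scaled"`, and the parameters.
#' @export
integrate_ode <- function(p, x0, times, atol = 1e-10, rtol = 1e-8) {
  stopifnot(inherits(p, "imm_params"))
  x0 <- check_state(x0, "x0")
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("times must be strictly increasing with at least two points")
  f <- function(t, x, parms) list(unname(scaled_rhs(p, x)))
  sol <- deSolve::ode(y = x0, times = times, func = f, parms = NULL,
                      method = "lsoda", atol = atol, rtol = rtol,
                      maxsteps = 100000)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed at t = ", max(sol[, 1]))
  states <- unname(sol[, -1, drop = FALSE])
  colnames(states) <- compartments()
  new_trajectory(times = sol[, 1], states = states, scale = "scaled",
                 params = p, method = "lsoda")
}

new_trajectory <- function(times, states, scale, params, method,
                           seed = NULL, dt = NULL) {
  structure(list(times = times, states = states, scale = scale,
                 params = params, method = method, seed = seed, dt = dt),
            class = "imm_trajectory")
}

#' @export
print.imm_trajectory <- function(x, ...) {
  cat(sprintf("<imm_trajectory> %s, %d time points on [%g, %g], %s units\n",
              x$method, length(x$times), min(x$times), max(x$times), x$scale))
  cat("final state:\n")
  print(signif(x$states[nrow(x$states), ], 6))
  invisible(x)
}

#' @export
as.data.frame.imm_trajectory <- function(x, ...) {
  data.frame(t = x$times, x$states, check.names = FALSE)
}
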