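#' Classify a final state against a set of attractors
#'
#' Assigns the nearest attractor in relative Euclidean distance, each
#' component normalised by `max(1, attractor component)`; returns
#' `"unresolved"` when the nearest distance exceeds `threshold`. Exact ties
#' are broken deterministically by attractor order and flagged.
#'
#' @param final_state scaled state (length 7).
#' @param attractors a list of `imm_steady_state` objects (or the full list
#'   from [steady_states()]).
#' @param threshold relative distance beyond which the run is unresolved.
#' @return A list with `label`, `distance`, and `tie`.
#' @export
classify_endpoint <- function(final_state, attractors, threshold = 0.5) {
  stopifnot(length(attractors) >= 1)
  x <- check_state(final_state, "final_state")
  d <- vapply(attractors, function(s) {
    a <- s$x
    sqrt(sum(((x - a) / pmax(1, abs(a)))^2))
  }, numeric(1))
  labs <- unname(vapply(attractors, function(s) s$label, character(1)))
  i <- which.min(d)
  tie <- sum(d == d[i]) > 1L
  if (d[i] > threshold)
    list(label = "unresolved", distance = unname(d[i]), tie = tie)
  else
    list(label = labs[i], distance = unname(d[i]), tie = tie)
}

# vectorised classification of an endpoint matrix (rows = runs, scaled)
classify_runs <- function(endpoints, attractors, threshold = 0.5) {
  labs <- character(nrow(endpoints))
  dist <- numeric(nrow(endpoints))
  for (i in seq_len(nrow(endpoints))) {
    cl <- classify_endpoint(endpoints[i, ], attractors, threshold)
    labs[i] <- cl$label
    dist[i] <- cl$distance
  }
  data.frame(label = labs, distance = dist)
}

#' Two-component Gaussian mixture fit (bimodal normal distribution)
#'
#' Expectation-maximisation fit of a two-component multivariate normal
#' mixture, with component means initialised at two supplied steady states
#' (counts scale) and equal initial weights. Convergence is declared when
#' the mean log-likelihood improves by less than `tol` per point;
#' the log-likelihood is asserted non-decreasing across iterations.
#' Degenerate outcomes (a component weight below `1e-4` or a numerically
#' singular covariance) are returned with `degenerate = TRUE`.
#'
#' @param sample numeric matrix (runs x d) of endpoint samples; a vector is
#'   treated as one-dimensional.
#' @param init two initial mean vectors: a list of two vectors, a 2 x d
#'   matrix, or two `imm_steady_state` objects (their `x` is scaled by
#'   `Omega`).
#' @param Omega scale applied to `imm_steady_state` initial means.
#' @param max_iter,tol EM iteration cap and per-point log-likelihood
#'   tolerance.
#' @return An `imm_bimodal` object: weights `w` (length 2, summing to 1),
#'   `means` (2 x d), `covs` (list of two d x d matrices), `loglik`,
#'   `loglik_trace`, `responsibilities`, `iterations`, `degenerate`.
#' @export
fit_bimodal <- function(sample, init, Omega = 1, max_iter = 500,
                        tol = 1e-8) {
  X <- as.matrix(sample)
  n <- nrow(X); d <- ncol(X)
  if (n < 50) stop("need at least 50 resolved endpoints")
  if (is.list(init) && inherits(init[[1]], "imm_steady_state"))
    init <- rbind(init[[1]]$x * Omega, init[[2]]$x * Omega)
  if (is.list(init)) init <- do.call(rbind, init)
  init <- as.matrix(init)
  stopifnot(nrow(init) == 2, ncol(init) == d)

  mu <- init
  if (max(diag(stats::cov(X))) < 1e-12)      # constant sample: nothing to fit
    return(structure(list(w = c(0.5, 0.5), means = init,
                          covs = rep(list(diag(0, d)), 2),
                          loglik = NA_real_, loglik_trace = numeric(0),
                          iterations = 0L, degenerate = TRUE),
                     class = "imm_bimodal"))
  base_cov <- stats::cov(X) + diag(1e-8 * max(diag(stats::cov(X)), 1), d)
  covs <- list(base_cov, base_cov)
  w <- c(0.5, 0.5)
  eps <- 1e-10
  ll_trace <- numeric(0)
  degenerate <- FALSE

  logdens <- function(mu_k, S_k) {
    ch <- tryCatch(chol(S_k), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    z <- forwardsolve(t(ch), t(X) - mu_k)
    -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
  }
  for (it in seq_len(max_iter)) {
    l1 <- logdens(mu[1, ], covs[[1]])
    l2 <- logdens(mu[2, ], covs[[2]])
    if (is.null(l1) || is.null(l2)) { degenerate <- TRUE; break }
    a1 <- log(w[1]) + l1
    a2 <- log(w[2]) + l2
    m <- pmax(a1, a2)
    ll <- sum(m + log(exp(a1 - m) + exp(a2 - m)))
    if (length(ll_trace) && ll < ll_trace[length(ll_trace)] - 1e-6 * abs(ll))
      stop("EM log-likelihood decreased; numerical failure")
    done <- length(ll_trace) &&
      (ll - ll_trace[length(ll_trace)]) < tol * n
    ll_trace <- c(ll_trace, ll)
    if (done) break
    r1 <- 1 / (1 + exp(a2 - a1))          # responsibilities, component 1
    r1 <- pmin(pmax(r1, eps), 1 - eps)
    w <- c(mean(r1), mean(1 - r1))
    if (min(w) < 1e-4) { degenerate <- TRUE; break }
    for (k in 1:2) {
      rk <- if (k == 1) r1 else 1 - r1
      mu[k, ] <- colSums(X * rk) / sum(rk)
      Xc <- sweep(X, 2, mu[k, ])
      Sk <- crossprod(Xc * rk, Xc) / sum(rk)
      Sk <- Sk + diag(1e-10 * max(diag(Sk), 1), d)
      covs[[k]] <- Sk
    }
  }
  structure(list(w = w / sum(w), means = mu, covs = covs,
                 loglik = if (length(ll_trace)) ll_trace[length(ll_trace)]
                          else NA_real_,
                 loglik_trace = ll_trace,
                 iterations = length(ll_trace),
                 degenerate = degenerate ||
                   any(!vapply(covs, function(S)
                     all(is.finite(S)) && det(S) > 0, logical(1)))),
            class = "imm_bimodal")
}

#' @export
print.imm_bimodal <- function(x, ...) {
  cat(sprintf("<imm_bimodal> weights %.3f / %.3f, loglik %.4g, %d iterations%s\n",
              x$w[1], x$w[2], x$loglik, x$iterations,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Bistable ensemble with endpoint classification and mixture fit
#'
#' Runs an Euler-Maruyama ensemble from a common initial condition,
#' classifies every endpoint against the stable steady states of the
#' deterministic model, and fits a two-component Gaussian mixture to a
#' chosen marginal of the endpoint sample when at least two attractors are
#' stable.
#'
#' @param p an [imm_params()] object.
#' @param x0 initial scaled state; counts are `Omega * x0`.
#' @param n_runs,t_max,dt,base_seed ensemble configuration (see
#'   [ensemble_em()]).
#' @param threshold classification threshold (see [classify_endpoint()]).
#' @param fit_margins compartment indices on which 1-D mixture fits are
#'   performed (in addition to the full 7-D fit).
#' @return An `imm_bistable` object: the ensemble, a `classification`
#'   data frame, a table of `counts` per label, the attractor list, and
#'   mixture fits (`fit_full`, `fit_margins`).
#' @export
bistable_ensemble <- function(p, x0, n_runs = 1000, t_max = 100, dt = 1e-3,
                              base_seed = 1, threshold = 0.5,
                              fit_margins = c(4, 6)) {
  stopifnot(inherits(p, "imm_params"))
  sts <- steady_states(p, find_s4 = FALSE)
  attr_set <- Filter(function(s) s$feasible && s$stability == "stable", sts)
  if (!length(attr_set)) stop("no stable steady state at these parameters")
  ens <- ensemble_em(p, p$Omega * check_state(x0, "x0"), t_max, dt = dt,
                     n_runs = n_runs, base_seed = base_seed,
                     checkpoints = c(t_max / 2, t_max))
  cls <- classify_runs(ens$endpoints / p$Omega, attr_set, threshold)
  counts <- table(factor(cls$label,
                         levels = c(vapply(attr_set, `[[`, "", "label"),
                                    "unresolved")))
  fit_full <- fit_margins_out <- NULL
  if (length(attr_set) >= 2 && n_runs >= 50) {
    ord <- order(-as.numeric(counts[seq_along(attr_set)]))
    top2 <- attr_set[ord[1:2]]
    fit_full <- tryCatch(
      fit_bimodal(ens$endpoints, top2, Omega = p$Omega),
      error = function(e) NULL)
    fit_margins_out <- lapply(fit_margins, function(j)
      tryCatch(fit_bimodal(ens$endpoints[, j, drop = FALSE],
                           rbind(top2[[1]]$x[j], top2[[2]]$x[j]) * p$Omega),
               error = function(e) NULL))
    names(fit_margins_out) <- compartments()[fit_margins]
  }
  structure(list(ensemble = ens, classification = cls, counts = counts,
                 attractors = attr_set, fit_full = fit_full,
                 fit_margins = fit_margins_out, threshold = threshold),
            class = "imm_bistable")
}

#' @export
print.imm_bistable <- function(x, ...) {
  cat("<imm_bistable> endpoint classification:\n")
  print(x$counts)
  if (!is.null(x$fit_full)) print(x$fit_full)
  invisible(x)
}

#' Basin-of-attraction probability map
#'
#' Over a grid of initial infected-cell and regulatory T-cell numbers (the
#' remaining compartments held fixed), estimates per cell the probability
#' that a stochastic trajectory ends in the basin of a designated outcome,
#' with binomial standard errors, and integrates the deterministic model
#' from the same initial condition to label the deterministic basin.
#'
#' @param p an [imm_params()] object.
#' @param f0_grid,treg0_grid scaled initial values of infected cells and
#'   regulatory T cells.
#' @param fixed named scaled values for the remaining compartments
#'   (defaults: `S = 18`, `T_in = 7.2`, others 0).
#' @param n_runs runs per cell.
#' @param t_max,dt,base_seed simulation configuration; cell `(i,j)` uses
#'   seeds offset deterministically from `base_seed`.
#' @param outcome target label (e.g. `"S1"`); matched against
#'   `label_base` so either quadratic root of a family counts.
#' @param threshold classification threshold.
#' @param noise_scale multiplies the diffusion (0 recovers the
#'   deterministic indicator map).
#' @return An `imm_basin_map`: data frame with columns `F0`, `Treg0`,
#'   `p_hat`, `se`, `n_runs`, `det_label`; `NA` probability where all runs
#'   were unresolved.
#' @export
basin_probability_map <- function(p, f0_grid, treg0_grid,
                                  fixed = c(S = 18, T_in = 7.2),
                                  n_runs = 50, t_max = 100, dt = 1e-3,
                                  base_seed = 1, outcome = "S1",
                                  threshold = 0.5, noise_scale = 1) {
  stopifnot(inherits(p, "imm_params"))
  sts <- steady_states(p, find_s4 = FALSE)
  attr_set <- Filter(function(s) s$feasible && s$stability == "stable", sts)
  if (!length(attr_set)) stop("no stable steady state at these parameters")
  base_state <- stats::setNames(numeric(7), compartments())
  base_state[names(fixed)] <- fixed
  out <- expand.grid(F0 = f0_grid, Treg0 = treg0_grid,
                     KEEP.OUT.ATTRS = FALSE)
  out$p_hat <- NA_real_; out$se <- NA_real_
  out$n_runs <- n_runs; out$det_label <- NA_character_
  is_outcome <- function(lab) {
    lb <- vapply(attr_set, function(s)
      if (identical(s$label, lab)) s$label_base else "", character(1))
    any(lb == outcome)
  }
  for (i in seq_len(nrow(out))) {
    x0 <- base_state
    x0["F"] <- out$F0[i]; x0["T_reg"] <- out$Treg0[i]
    # deterministic basin label
    tr <- integrate_ode(p, x0, seq(0, max(4 * t_max, 400), length.out = 9))
    det <- classify_endpoint(tr$states[9, ], attr_set, threshold)
    out$det_label[i] <- det$label
    ens <- ensemble_em(p, p$Omega * x0, t_max, dt = dt, n_runs = n_runs,
                       base_seed = base_seed + 1000L * (i - 1L),
                       checkpoints = t_max, noise_scale = noise_scale)
    cls <- classify_runs(ens$endpoints / p$Omega, attr_set, threshold)
    resolved <- cls$label != "unresolved"
    if (!any(resolved)) next
    hit <- vapply(cls$label[resolved], is_outcome, logical(1))
    ph <- mean(hit)
    out$p_hat[i] <- ph
    out$se[i] <- sqrt(ph * (1 - ph) / sum(resolved))
  }
  structure(out, class = c("imm_basin_map", "data.frame"),
            outcome = outcome, f0_grid = f0_grid, treg0_grid = treg0_grid,
            params = p)
}
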