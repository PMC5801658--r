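#' Plot a trajectory
#'
#' Time courses of the seven compartments on a shared axis (base graphics).
#'
#' @param x an `imm_trajectory`.
#' @param which compartment indices to draw.
#' @param log use a logarithmic y axis (`"y"`) or not (`""`).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.imm_trajectory <- function(x, which = 1:7, log = "", ...) {
  graphics::matplot(x$times, x$states[, which, drop = FALSE], type = "l",
                    lty = 1, xlab = "time",
                    ylab = paste0("state (", x$scale, ")"), log = log, ...)
  graphics::legend("topright", legend = compartments()[which],
                   col = seq_along(which), lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Plot ensemble mean with one-standard-deviation bands
#'
#' @param x an `imm_ensemble`.
#' @param which compartment index.
#' @param ... passed to [graphics::plot()].
#' @export
plot.imm_ensemble <- function(x, which = 4, ...) {
  m <- x$mean[, which]
  s <- sqrt(pmax(x$var[, which], 0))
  graphics::plot(x$times, m, type = "l", xlab = "time",
                 ylab = compartments()[which],
                 ylim = range(m - s, m + s), ...)
  graphics::polygon(c(x$times, rev(x$times)), c(m - s, rev(m + s)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(x$times, m)
  invisible(x)
}

#' Heat map of a basin-probability map
#'
#' Image of the per-cell outcome probability with the deterministic basin
#' boundary overlaid (boundary cells separate deterministic labels).
#'
#' @param x an `imm_basin_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.imm_basin_map <- function(x, ...) {
  f0 <- attr(x, "f0_grid"); t0 <- attr(x, "treg0_grid")
  z <- matrix(x$p_hat, length(f0), length(t0))
  graphics::image(f0, t0, z, xlab = "F(0)", ylab = "T_reg(0)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  det <- matrix(as.integer(factor(x$det_label)), length(f0), length(t0))
  if (length(unique(as.vector(det))) > 1)
    graphics::contour(f0, t0, det, add = TRUE, drawlabels = FALSE,
                      lwd = 2, col = "black",
                      levels = seq(1.5, max(det) - 0.5))
  invisible(x)
}

#' Heat map of a variance map
#'
#' @param x an `imm_variance_map`.
#' @param log_z plot `log10` of the variance.
#' @param ... passed to [graphics::image()].
#' @export
plot.imm_variance_map <- function(x, log_z = TRUE, ...) {
  a1 <- attr(x, "axis1"); a2 <- attr(x, "axis2")
  z <- matrix(x$variance, length(a1$values), length(a2$values))
  if (log_z) z <- log10(z)
  graphics::image(a1$values, a2$values, z, xlab = a1$name, ylab = a2$name,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Histogram of an endpoint marginal with the fitted mixture overlaid
#'
#' @param x an `imm_bistable` result.
#' @param which compartment index (must be one of the fitted margins).
#' @param breaks passed to [graphics::hist()].
#' @param ... passed to [graphics::hist()].
#' @export
plot.imm_bistable <- function(x, which = 4, breaks = 50, ...) {
  comp <- compartments()[which]
  y <- x$ensemble$endpoints[, which]
  h <- graphics::hist(y, breaks = breaks, freq = FALSE,
                      xlab = paste(comp, "(counts)"), main = "", ...)
  fit <- x$fit_margins[[comp]]
  if (!is.null(fit)) {
    xs <- seq(min(y), max(y), length.out = 400)
    dens <- fit$w[1] * stats::dnorm(xs, fit$means[1, 1],
                                    sqrt(fit$covs[[1]][1, 1])) +
      fit$w[2] * stats::dnorm(xs, fit$means[2, 1],
                              sqrt(fit$covs[[2]][1, 1]))
    graphics::lines(xs, dens, col = "firebrick", lwd = 2)
  }
  invisible(x)
}
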