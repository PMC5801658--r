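#' Model parameters for the within-host autoimmunity model
#'
#' Constructs and validates the full parameter set of the seven-compartment
#' immune model. Rates carrying a tilde in the usual macroscopic notation
#' (e.g. the scaled infection rate \eqn{\tilde\beta}) are stored with a
#' `_t` suffix; the corresponding copy-number (count-form) rates are derived
#' deterministically from the system size `Omega` by [count_rates()].
#'
#' The seven compartments are, in order: susceptible organ cells (S),
#' infected cells (F), naive T cells (T_in), regulatory T cells (T_reg),
#' normal activated T cells (T_nor), autoreactive T cells (T_aut), and
#' interleukin-2 (I).
#'
#' Default values follow the published parameter table of the model. Several
#' entries of that table are typeset ambiguously (fractions collapsed to
#' digit strings); the defaults here are the reading that reproduces the
#' reported dynamical regimes, in particular the coexistence of a stable
#' disease-free state and a stable autoimmune spiral at `sigma2 = 1`.
#' See the package vignette for the full discussion. Every value can be
#' overridden, either directly or via a YAML/JSON file ([read_params()]);
#' fractions may be given as strings such as `"40/9"`.
#'
#' @param b1,d1 per-capita linear birth/death rates of susceptible cells;
#'   `b1 - d1 = r > 0` is the logistic growth rate.
#' @param b2_t,d2_t scaled quadratic birth/death coefficients; `d2_t - b2_t
#'   = r/N > 0` fixes the carrying capacity `N`.
#' @param beta_t scaled infection rate.
#' @param mu_a_t scaled rate at which autoreactive T cells kill cells.
#' @param mu_F_t scaled rate at which normal T cells kill infected cells.
#' @param d_F infected-cell death rate.
#' @param lambda_in_t,d_in scaled influx and death rate of naive T cells.
#' @param alpha_t scaled activation rate of naive T cells by infected cells.
#' @param p1,p2 fractions of activated T cells becoming regulatory and
#'   normal activated cells; the remainder `1 - p1 - p2` become autoreactive.
#' @param lambda_r_t,d_r scaled influx and death rate of regulatory T cells.
#' @param rho1_t,rho2_t,rho3_t scaled IL-2-driven proliferation rates of
#'   regulatory, normal, and autoreactive T cells.
#' @param d_n,d_a death rates of normal and autoreactive T cells.
#' @param delta_t scaled rate of suppression of autoreactive T cells by
#'   regulatory T cells.
#' @param sigma1,sigma2 IL-2 production rates by normal and autoreactive
#'   T cells.
#' @param d_i IL-2 decay rate.
#' @param Omega system size (scale factor between macroscopic concentrations
#'   `x` and copy numbers `n = Omega * x`); must be positive.
#' @param ... further named arguments are an error (guards against typos).
#'
#' @return An object of class `imm_params`: a named list of numeric scalars.
#' @examples
#' p <- imm_params(sigma2 = 1)
#' p$mu_a_t
#' @export
imm_params <- function(b1 = 2.5, d1 = 0.5, b2_t = 0.1, d2_t = 0.2,
                       beta_t = 0.1, mu_a_t = 4 / 9, mu_F_t = 4 / 3,
                       d_F = 2.2, lambda_in_t = 18, d_in = 2,
                       alpha_t = 0.04, p1 = 0.4, p2 = 0.4,
                       lambda_r_t = 108, d_r = 0.8,
                       rho1_t = 10 / 9, rho2_t = 4 / 45, rho3_t = 2 / 9,
                       d_n = 2, d_a = 0.002, delta_t = 1 / 4500,
                       sigma1 = 0.3, sigma2 = 0.4, d_i = 1.2,
                       Omega = 1000, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown parameter(s): ", paste(names(extra), collapse = ", "))
  p <- list(b1 = b1, d1 = d1, b2_t = b2_t, d2_t = d2_t, beta_t = beta_t,
            mu_a_t = mu_a_t, mu_F_t = mu_F_t, d_F = d_F,
            lambda_in_t = lambda_in_t, d_in = d_in, alpha_t = alpha_t,
            p1 = p1, p2 = p2, lambda_r_t = lambda_r_t, d_r = d_r,
            rho1_t = rho1_t, rho2_t = rho2_t, rho3_t = rho3_t,
            d_n = d_n, d_a = d_a, delta_t = delta_t,
            sigma1 = sigma1, sigma2 = sigma2, d_i = d_i, Omega = Omega)
  p <- lapply(p, parse_rate)
  validate_params(p)
  structure(p, class = "imm_params")
}

# accept numbers or fraction strings like "40/9"
parse_rate <- function(v) {
  if (is.character(v)) {
    v <- gsub("[[:space:]]", "", v)
    if (grepl("^[-+0-9.eE]+/[-+0-9.eE]+$", v)) {
      parts <- strsplit(v, "/", fixed = TRUE)[[1]]
      return(as.numeric(parts[1]) / as.numeric(parts[2]))
    }
    v <- as.numeric(v)
  }
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
    stop("parameter values must be finite numeric scalars")
  as.numeric(v)
}

validate_params <- function(p) {
  nonneg <- setdiff(names(p), "Omega")
  bad <- nonneg[vapply(p[nonneg], function(v) v < 0, logical(1))]
  if (length(bad))
    stop("negative rate(s): ", paste(bad, collapse = ", "))
  if (p$p1 + p$p2 > 1 + 1e-12)
    stop("activation fractions must satisfy p1 + p2 <= 1")
  if (p$Omega <= 0) stop("Omega must be positive")
  if (p$b1 <= p$d1)
    stop("logistic growth requires b1 > d1")
  if (p$d2_t <= p$b2_t)
    stop("logistic saturation requires d2_t > b2_t")
  invisible(p)
}

#' Update a parameter set
#'
#' Returns a copy of `p` with the named entries replaced (and re-validated).
#'
#' @param p an [imm_params()] object.
#' @param ... named replacements, e.g. `sigma2 = 1`.
#' @return A new `imm_params` object.
#' @export
update_params <- function(p, ...) {
  stopifnot(inherits(p, "imm_params"))
  repl <- list(...)
  unknown <- setdiff(names(repl), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(repl)] <- lapply(repl, parse_rate)
  validate_params(p)
  structure(p, class = "imm_params")
}

#' Count-form (copy-number) rates
#'
#' Converts the scaled (macroscopic) rates into the copy-number rates that
#' define the jump process and the SDE: bimolecular rates scale as
#' `rate / Omega`, influxes as `rate * Omega`, linear rates are unchanged.
#'
#' @param p an [imm_params()] object.
#' @return A named numeric vector with elements `b1, b2, d1, d2, beta, mu_a,
#'   mu_F, d_F, lambda_in, d_in, alpha, p1, p2, lambda_r, d_r, rho1, rho2,
#'   rho3, d_n, d_a, delta, sigma1, sigma2, d_i, Omega`.
#' @export
count_rates <- function(p) {
  stopifnot(inherits(p, "imm_params"))
  O <- p$Omega
  c(b1 = p$b1, b2 = p$b2_t / O, d1 = p$d1, d2 = p$d2_t / O,
    beta = p$beta_t / O, mu_a = p$mu_a_t / O, mu_F = p$mu_F_t / O,
    d_F = p$d_F, lambda_in = p$lambda_in_t * O, d_in = p$d_in,
    alpha = p$alpha_t / O, p1 = p$p1, p2 = p$p2,
    lambda_r = p$lambda_r_t * O, d_r = p$d_r,
    rho1 = p$rho1_t / O, rho2 = p$rho2_t / O, rho3 = p$rho3_t / O,
    d_n = p$d_n, d_a = p$d_a, delta = p$delta_t / O,
    sigma1 = p$sigma1, sigma2 = p$sigma2, d_i = p$d_i, Omega = O)
}

#' @export
print.imm_params <- function(x, ...) {
  cat("<imm_params> seven-compartment autoimmunity model\n")
  v <- unlist(x)
  nm <- names(v)
  for (i in seq(1, length(v), by = 5)) {
    j <- seq(i, min(i + 4, length(v)))
    cat(" ", paste(sprintf("%-11s= %-10.6g", nm[j], v[j]), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Read / write parameter files
#'
#' Flat YAML or JSON mappings of the [imm_params()] field names; values may
#' be numbers or fraction strings (`"40/9"`). Missing fields take defaults.
#' The format is chosen from the file extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param path file path.
#' @return `read_params()` returns an `imm_params` object; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(imm_params, as.list(vals))
}

#' @rdname read_params
#' @param p an [imm_params()] object to serialise.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "imm_params"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(unclass(p), path, precision = 15)
  }
  invisible(path)
}

# canonical compartment names, used throughout
compartments <- function() c("S", "F", "T_in", "T_reg", "T_nor", "T_aut", "I")

check_state <- function(x, what = "state") {
  if (!is.numeric(x) || length(x) != 7L)
    stop(what, " must be a numeric vector of length 7")
  if (any(!is.finite(x)))
    stop(what, " has non-finite components")
  unname(x)
}
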