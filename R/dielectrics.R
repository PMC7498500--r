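## Dielectric dispersion and admittivity. Tissue spectra follow the
## four-term Cole-Cole model
##   eps_hat(w) = eps_inf + sum_n d_eps_n / (1 + (j w tau_n)^(1-alpha_n))
##                + sigma_ionic / (j w eps0)
## with eps_r = Re(eps_hat) and sigma = -w eps0 Im(eps_hat); the complex
## admittivity entering the frequency-dependent Poisson operator is
## y = sigma + j w eps0 eps_r.

#' Vacuum permittivity (F/m)
#' @export
EPS0 <- 8.85e-12

#' Four-term Cole-Cole parameter set
#'
#' @param eps_inf high-frequency relative permittivity (dimensionless).
#' @param delta_eps dispersion magnitudes, up to 4 terms.
#' @param tau relaxation times (s), same length as `delta_eps`.
#' @param alpha broadening exponents in `[0, 1)`, same length.
#' @param sigma_ionic static ionic conductivity (S/m).
#' @return object of class `cole_cole_params`.
#' @export
cole_cole_params <- function(eps_inf, delta_eps, tau, alpha, sigma_ionic) {
  stopifnot(length(delta_eps) == length(tau),
            length(alpha) == length(tau))
  if (any(tau <= 0)) stop("tau must be positive")
  if (any(alpha < 0 | alpha >= 1)) stop("alpha must be in [0, 1)")
  if (any(delta_eps < 0)) stop("delta_eps must be non-negative")
  if (sigma_ionic < 0) stop("sigma_ionic must be non-negative")
  structure(list(eps_inf = eps_inf, delta_eps = delta_eps, tau = tau,
                 alpha = alpha, sigma_ionic = sigma_ionic),
            class = "cole_cole_params")
}

#' Evaluate a Cole-Cole dispersion at a frequency
#'
#' Principal-branch complex power `(j w tau)^(1-alpha)` with
#' `j^x = exp(j pi x / 2)` (standard Cole-Cole convention, positive loss).
#' `f = 0` is handled by the analytic limit: the `1/(j w)` ionic term
#' contributes only to the conductivity, every dispersion term is fully
#' relaxed, so `sigma = sigma_ionic` and `eps_r = eps_inf + sum delta_eps`.
#'
#' @param params a [cole_cole_params()] (or a character tissue name
#'   resolved through [tissue_table()]).
#' @param f frequency in Hz (vectorized, `f >= 0`).
#' @return list with numeric vectors `sigma` (S/m) and `eps_r`.
#' @export
cole_cole_eval <- function(params, f) {
  if (is.character(params)) params <- tissue_table()[[params]]$cole_cole
  stopifnot(inherits(params, "cole_cole_params"))
  f <- as.numeric(f)
  if (any(f < 0)) stop("f must be non-negative")
  sigma <- numeric(length(f)); eps_r <- numeric(length(f))
  z <- f == 0
  if (any(z)) {
    sigma[z] <- params$sigma_ionic
    eps_r[z] <- params$eps_inf + sum(params$delta_eps)
  }
  if (any(!z)) {
    w <- 2 * pi * f[!z]
    eh <- rep(params$eps_inf + 0i, length(w))
    for (k in seq_along(params$tau)) {
      x <- 1 - params$alpha[k]
      jwt <- (w * params$tau[k])^x * exp(1i * pi * x / 2)
      eh <- eh + params$delta_eps[k] / (1 + jwt)
    }
    eh <- eh + params$sigma_ionic / (1i * w * EPS0)
    eps_r[!z] <- Re(eh)
    sigma[!z] <- -w * EPS0 * Im(eh)
  }
  list(sigma = sigma, eps_r = eps_r)
}

#' Complex admittivity sigma + j w eps0 eps_r
#'
#' @param sigma conductivity in S/m: a scalar or a symmetric 3x3 tensor.
#' @param eps_r relative permittivity (scalar, or 3x3 tensor matching
#'   `sigma`).
#' @param f frequency (Hz).
#' @return object of class `admittivity` with fields `sigma`, `eps_r`,
#'   `omega`, and `value` = complex scalar or complex 3x3 tensor.
#' @export
admittivity_of <- function(sigma, eps_r, f) {
  w <- 2 * pi * f
  if (is.matrix(sigma)) {
    stopifnot(all(dim(sigma) == c(3, 3)))
    if (max(abs(sigma - t(sigma))) > 1e-12 * max(abs(sigma)))
      stop("conductivity tensor must be symmetric")
    if (any(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("conductivity tensor must be positive definite")
    if (!is.matrix(eps_r)) eps_r <- diag(3) * eps_r
    value <- sigma + 1i * w * EPS0 * eps_r
  } else {
    if (sigma < 0) stop("sigma must be non-negative")
    if (eps_r < 0) stop("eps_r must be non-negative")
    if (eps_r > 0 && eps_r < 1)
      warning("eps_r < 1 is unphysical for a passive medium")
    value <- complex(real = sigma, imaginary = w * EPS0 * eps_r)
  }
  structure(list(sigma = sigma, eps_r = eps_r, omega = w, value = value),
            class = "admittivity")
}

#' Admittivity of a packaged tissue at a frequency
#'
#' Convenience wrapper: Cole-Cole evaluation followed by
#' [admittivity_of()].
#'
#' @param tissue tissue name, see [tissue_table()].
#' @param f frequency (Hz).
#' @return an `admittivity`.
#' @export
tissue_admittivity <- function(tissue, f) {
  ce <- cole_cole_eval(tissue, f)
  admittivity_of(ce$sigma, ce$eps_r, f)
}

#' Axisymmetric anisotropic conductivity tensor
#'
#' Builds the symmetric tensor with eigenvalue `longitudinal` along
#' `direction` and `transverse` in the perpendicular plane, e.g. for
#' white-matter fiber anisotropy.
#'
#' @param longitudinal conductivity along the axis (S/m).
#' @param transverse conductivity across the axis (S/m).
#' @param direction axis vector (normalized internally).
#' @return symmetric 3x3 matrix.
#' @export
anisotropic_tensor <- function(longitudinal, transverse, direction) {
  stopifnot(longitudinal > 0, transverse > 0, length(direction) == 3)
  d <- direction / sqrt(sum(direction^2))
  transverse * diag(3) + (longitudinal - transverse) * tcrossprod(d)
}

## Gabriel-style four-term Cole-Cole constants for the packaged tissues.
## "ringer" is a synthetic stand-in (CSF-like dispersion, ionic
## conductivity of physiological saline); it has no literature parameter
## set.
.tissue_db <- function() {
  cc <- function(...) cole_cole_params(...)
  list(
    grey = list(
      sigma_static = 0.27,
      cole_cole = cc(4, c(45, 400, 2e5, 4.5e7),
                     c(7.958e-12, 15.915e-9, 106.103e-6, 5.305e-3),
                     c(0.10, 0.15, 0.22, 0.00), 0.02)),
    white = list(
      sigma_static = 0.12,
      cole_cole = cc(4, c(32, 100, 4e4, 3.5e7),
                     c(7.958e-12, 7.958e-9, 53.052e-6, 7.958e-3),
                     c(0.10, 0.10, 0.30, 0.02), 0.02)),
    csf = list(
      sigma_static = 1.65,
      cole_cole = cc(4, c(65, 40),
                     c(7.958e-12, 1.592e-9),
                     c(0.10, 0.00), 2.0)),
    skull = list(
      sigma_static = 0.01,
      cole_cole = cc(2.5, c(10, 180, 5e3, 1e5),
                     c(13.263e-12, 79.577e-9, 159.155e-6, 15.915e-3),
                     c(0.20, 0.20, 0.20, 0.00), 0.02)),
    scalp = list(
      sigma_static = 0.46,
      cole_cole = cc(4, c(32, 1100),
                     c(7.234e-12, 32.481e-9),
                     c(0.00, 0.20), 2e-4)),
    ringer = list(
      sigma_static = 1.5,
      cole_cole = cc(4, c(65, 40),
                     c(7.958e-12, 1.592e-9),
                     c(0.10, 0.00), 1.5))
  )
}

#' Packaged tissue dielectric table
#'
#' Named entries (`grey`, `white`, `csf`, `skull`, `scalp`, `ringer`),
#' each a list with `sigma_static` (S/m, low-frequency literature
#' conductivity) and `cole_cole` (a [cole_cole_params()]). Entries can be
#' overridden or extended from a JSON file with entries of the form
#' `{"name": {"eps_inf":, "delta_eps":[], "tau":[], "alpha":[],
#' "sigma_ionic":, "sigma_static":}}` or a purely static
#' `{"name": {"sigma":, "eps_r":}}`.
#'
#' @param overrides optional path to a JSON override file.
#' @return named list of tissue entries.
#' @export
tissue_table <- function(overrides = NULL) {
  db <- .tissue_db()
  if (!is.null(overrides)) {
    ov <- jsonlite::read_json(overrides, simplifyVector = TRUE)
    for (nm in names(ov)) {
      e <- ov[[nm]]
      if (!is.null(e$sigma) && is.null(e$sigma_ionic)) {
        ## static entry: a degenerate Cole-Cole with no dispersion terms
        db[[nm]] <- list(
          sigma_static = e$sigma,
          cole_cole = cole_cole_params(e$eps_r, numeric(0), numeric(0),
                                       numeric(0), e$sigma))
      } else {
        db[[nm]] <- list(
          sigma_static = if (!is.null(e$sigma_static)) e$sigma_static
                         else e$sigma_ionic,
          cole_cole = cole_cole_params(e$eps_inf, e$delta_eps, e$tau,
                                       e$alpha, e$sigma_ionic))
      }
    }
  }
  db
}
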