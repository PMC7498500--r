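## Analytical dipole potential in concentric spherical shells with complex
## admittivities, via a Legendre series: in each layer the n-th harmonic
## is A (r/r_s)^n + B (r_out_prev/r)^(n+1) (normalized so coefficients
## stay O(1) at large n), the innermost layer carries the infinite-medium
## source expansion, and the 2L-1 coefficients per harmonic follow from
## potential/current continuity at the interfaces and zero normal current
## at the outer surface. The dipole moment is decomposed into a radial
## component (m = 0 terms, P_n) and a tangential component (m = 1 terms,
## P_n^1 cos azimuth).

#' Concentric-sphere head model for the analytic dipole series
#'
#' @param radii strictly increasing layer outer radii (m); classically 4
#'   layers (brain, CSF, skull, scalp).
#' @param admittivities complex (or real) admittivity per layer (S/m):
#'   sigma for the resistive model, sigma + j w eps0 eps_r for the
#'   capacitive one.
#' @param n_terms series truncation (default 1000).
#' @return object of class `four_sphere_model`.
#' @export
four_sphere_model <- function(radii, admittivities, n_terms = 1000L) {
  radii <- as.numeric(radii)
  if (any(diff(radii) <= 0) || any(radii <= 0))
    stop("radii must be positive and strictly increasing")
  admittivities <- as.complex(admittivities)
  stopifnot(length(admittivities) == length(radii), n_terms >= 1)
  if (any(admittivities == 0)) stop("admittivities must be nonzero")
  structure(list(radii = radii, y = admittivities,
                 n_terms = as.integer(n_terms)),
            class = "four_sphere_model")
}

## per-harmonic layer coefficients: solves the (2L-1) x (2L-1) interface
## system; returns function of n -> coefficient vector
.layer_coefficients <- function(model, rz) {
  r <- model$radii; y <- model$y; L <- length(r)
  ## unknowns: A_1, (A_s, B_s) for s = 2..L
  function(n, c_src) {
    ## c_src: source strength so that phi_src(r) = c_src * (rz/r)^(n-1)/r^2
    nu <- 2L * L - 1L
    M <- matrix(0i, nu, nu); rhs <- complex(nu)
    idxA <- function(s) if (s == 1L) 1L else 2L * (s - 1L)
    idxB <- function(s) 2L * s - 1L
    Sval <- function(rr) c_src * (rz / rr)^(n - 1) / rr^2
    Sder <- function(rr) -(n + 1) / rr * Sval(rr)
    row <- 0L
    for (k in seq_len(L - 1L)) {
      rk <- r[k]
      ## continuity of phi
      row <- row + 1L
      M[row, idxA(k)] <- (rk / r[k])^n   # = 1
      if (k > 1L) M[row, idxB(k)] <- (r[k - 1L] / rk)^(n + 1)
      M[row, idxA(k + 1L)] <- -(rk / r[k + 1L])^n
      M[row, idxB(k + 1L)] <- -1
      if (k == 1L) rhs[row] <- -Sval(rk)
      ## continuity of y dphi/dr
      row <- row + 1L
      M[row, idxA(k)] <- y[k] * n / rk
      if (k > 1L) M[row, idxB(k)] <- -y[k] * (n + 1) / rk *
          (r[k - 1L] / rk)^(n + 1)
      M[row, idxA(k + 1L)] <- -y[k + 1L] * n / rk * (rk / r[k + 1L])^n
      M[row, idxB(k + 1L)] <- y[k + 1L] * (n + 1) / rk
      if (k == 1L) rhs[row] <- -y[1L] * Sder(rk)
    }
    ## outer Neumann: dphi_L/dr (r_L) = 0
    row <- row + 1L
    rl <- r[L]
    M[row, idxA(L)] <- n / rl
    if (L > 1L) M[row, idxB(L)] <- -(n + 1) / rl * (r[L - 1L] / rl)^(n + 1)
    else rhs[row] <- -Sder(rl)
    if (L == 1L) {
      ## single layer: one unknown A_1 from the outer BC alone
      return(solve(M[nu, nu, drop = FALSE], rhs[nu]))
    }
    solve(M, rhs)
  }
}

#' Analytic dipole potential in a layered sphere
#'
#' @param model a [four_sphere_model()].
#' @param dipole_position length-3 position (m), strictly inside the
#'   innermost layer.
#' @param dipole_moment length-3 moment vector (A m).
#' @param points `n` x 3 evaluation points, inside or on the outer sphere.
#' @return complex potential (V) per point.
#' @export
dipole_potential <- function(model, dipole_position, dipole_moment,
                             points) {
  r <- model$radii; y <- model$y; L <- length(r)
  pos <- as.numeric(dipole_position)
  mom <- as.numeric(dipole_moment)
  pts <- matrix(as.numeric(points), ncol = 3L)
  rz <- sqrt(sum(pos^2))
  if (rz >= r[1]) stop("dipole must lie strictly inside the innermost layer")
  rp <- sqrt(rowSums(pts^2))
  if (any(rp > r[L] * (1 + 1e-9))) stop("points outside the outer sphere")

  ## frame: zhat = radial axis through the dipole (moment direction if the
  ## dipole sits at the center), that = tangential moment direction
  zhat <- if (rz > 1e-15) pos / rz else mom / sqrt(sum(mom^2))
  p_rad <- sum(mom * zhat)
  t_vec <- mom - p_rad * zhat
  p_tan <- sqrt(sum(t_vec^2))
  that <- if (p_tan > 1e-300) t_vec / p_tan else c(0, 0, 0)

  ct <- pmin(1, pmax(-1, (pts %*% zhat)[, 1] / pmax(rp, 1e-300)))
  st <- sqrt(pmax(0, 1 - ct^2))
  ## azimuth of each point relative to that (in the plane normal to zhat)
  perp <- pts - outer((pts %*% zhat)[, 1], zhat)
  pn <- sqrt(rowSums(perp^2))
  cphi <- ifelse(pn > 1e-300, (perp %*% that)[, 1] / pn, 0)

  layer_of <- findInterval(rp, r[-L], rightmost.closed = FALSE) + 1L
  layer_of <- pmin(layer_of, L)
  coeff <- .layer_coefficients(model, rz)

  np <- nrow(pts)
  out <- complex(np)
  ## Legendre recurrences
  Pnm1 <- rep(1, np); Pn <- ct              # P_0, P_1
  P1nm1 <- rep(0, np); P1n <- st            # P^1_0 = 0, P^1_1 = sin
  c0 <- 1 / (4 * pi * y[1])
  for (n in seq_len(model$n_terms)) {
    if (n > 1L) {
      Pnew <- ((2 * n - 1) * ct * Pn - (n - 1) * Pnm1) / n
      Pnm1 <- Pn; Pn <- Pnew
      P1new <- ((2 * n - 1) * ct * P1n - n * P1nm1) / (n - 1)
      P1nm1 <- P1n; P1n <- P1new
    }
    for (part in c("rad", "tan")) {
      p_amp <- if (part == "rad") p_rad else p_tan
      if (p_amp == 0) next
      c_src <- if (part == "rad") c0 * p_amp * n else c0 * p_amp
      cf <- coeff(n, c_src)
      ang <- if (part == "rad") Pn else P1n * cphi
      ## evaluate radial profile per point
      val <- complex(np)
      for (s in seq_len(L)) {
        sel <- layer_of == s
        if (!any(sel)) next
        A <- cf[if (s == 1L) 1L else 2L * (s - 1L)]
        radial <- A * (rp[sel] / r[s])^n
        if (s > 1L) {
          B <- cf[2L * s - 1L]
          radial <- radial + B * (r[s - 1L] / rp[sel])^(n + 1)
        } else {
          radial <- radial + c_src * (rz / rp[sel])^(n - 1) / rp[sel]^2
        }
        val[sel] <- radial
      }
      out <- out + val * ang
    }
  }
  out
}

## independent closed-form oracle: homogeneous sphere (radius R,
## admittivity y) with an interior dipole; explicit image-series
## coefficients C_n = c_n (n+1)/n / R^(2n+1), no linear solves. Used by
## the test suite to validate the general layered solver.
homogeneous_sphere_dipole <- function(R, y, dipole_position, dipole_moment,
                                      points, n_terms = 1000L) {
  pos <- as.numeric(dipole_position); mom <- as.numeric(dipole_moment)
  pts <- matrix(as.numeric(points), ncol = 3L)
  rz <- sqrt(sum(pos^2))
  rp <- sqrt(rowSums(pts^2))
  zhat <- if (rz > 1e-15) pos / rz else mom / sqrt(sum(mom^2))
  p_rad <- sum(mom * zhat)
  t_vec <- mom - p_rad * zhat
  p_tan <- sqrt(sum(t_vec^2))
  that <- if (p_tan > 1e-300) t_vec / p_tan else c(0, 0, 0)
  ct <- pmin(1, pmax(-1, (pts %*% zhat)[, 1] / pmax(rp, 1e-300)))
  st <- sqrt(pmax(0, 1 - ct^2))
  perp <- pts - outer((pts %*% zhat)[, 1], zhat)
  pn <- sqrt(rowSums(perp^2))
  cphi <- ifelse(pn > 1e-300, (perp %*% that)[, 1] / pn, 0)
  np <- nrow(pts)
  out <- complex(np)
  Pnm1 <- rep(1, np); Pn <- ct
  P1nm1 <- rep(0, np); P1n <- st
  c0 <- 1 / (4 * pi * y)
  for (n in seq_len(n_terms)) {
    if (n > 1L) {
      Pnew <- ((2 * n - 1) * ct * Pn - (n - 1) * Pnm1) / n
      Pnm1 <- Pn; Pn <- Pnew
      P1new <- ((2 * n - 1) * ct * P1n - n * P1nm1) / (n - 1)
      P1nm1 <- P1n; P1n <- P1new
    }
    for (part in c("rad", "tan")) {
      p_amp <- if (part == "rad") p_rad else p_tan
      if (p_amp == 0) next
      c_src <- if (part == "rad") c0 * p_amp * n else c0 * p_amp
      ang <- if (part == "rad") Pn else P1n * cphi
      direct <- c_src * (rz / rp)^(n - 1) / rp^2
      refl <- c_src * ((n + 1) / n) * (rz / R)^(n - 1) * (rp / R)^n / R^2
      out <- out + (direct + refl) * ang
    }
  }
  out
}

#' Relative difference between two potential samples
#'
#' `RD = (1/N) sum_i |phi_i - psi_i| / max |psi|`: the mean absolute
#' deviation normalized by the peak reference magnitude (complex inputs
#' use the modulus).
#'
#' @param phi numeric/complex vector (e.g. the FEM solution).
#' @param psi reference vector of the same length (e.g. the analytic
#'   solution).
#' @return dimensionless scalar.
#' @export
relative_difference <- function(phi, psi) {
  stopifnot(length(phi) == length(psi))
  mx <- max(Mod(psi))
  if (mx == 0) stop("reference is identically zero")
  mean(Mod(phi - psi)) / mx
}

#' FEM-versus-analytic validation sweep on the four-sphere model
#'
#' For each dipole depth and orientation: solves the complex-block FEM on
#' the supplied mesh and the analytic series with identical admittivities,
#' evaluates both at quasi-uniform points on the brain/CSF interface
#' radius, and reports the relative difference.
#'
#' @param mesh a four-layer sphere [tet_mesh()] with cell markers 1..4
#'   (inner to outer) matching `radii`.
#' @param radii the four layer radii (m), inner to outer.
#' @param admittivities complex admittivity per layer (S/m), inner to
#'   outer (e.g. from [tissue_admittivity()]).
#' @param depths dipole depths below the brain surface (m).
#' @param orientations subset of `"radial"`, `"tangential"`, `"deg45"`.
#' @param n_points evaluation points on the brain/CSF surface.
#' @param current,separation monopole magnitude (A) and spacing (m) of the
#'   FEM dipole; the analytic side uses the ideal moment
#'   `current * separation`.
#' @param n_terms analytic series truncation.
#' @param tol,max_iter,preconditioner solver controls (GMRES).
#' @param out_csv optional path: write the RD table as CSV.
#' @param verbose print progress.
#' @return data.frame with columns depth, orientation, rd.
#' @export
validate_study1 <- function(mesh, radii, admittivities,
                            depths = c(1e-3, 2e-3, 3e-3, 4e-3, 5e-3),
                            orientations = c("radial", "tangential",
                                             "deg45"),
                            n_points = 1000L, current = 100e-6,
                            separation = 1e-3, n_terms = 1000L,
                            tol = 1e-8, max_iter = 400L,
                            preconditioner = "chol", out_csv = NULL,
                            verbose = FALSE) {
  stopifnot(length(radii) == 4L, length(admittivities) == 4L)
  mat <- setNames(as.list(as.complex(admittivities)),
                  as.character(1:4))
  system0 <- assemble_complex_block(mesh, mat, order = 1L)
  locator <- mesh_locator(mesh)
  pts <- surface_sample_points(radii[1], n_points)
  model <- four_sphere_model(radii, admittivities, n_terms)
  dirs <- list(radial = c(0, 0, 1), tangential = c(1, 0, 0),
               deg45 = c(1, 0, 1) / sqrt(2))
  res <- data.frame()
  for (d in depths) for (o in orientations) {
    pos <- c(0, 0, radii[1] - d)
    u <- dirs[[o]]
    sys <- assemble_source_rhs(system0, dipole_source(pos, u, current,
                                                      separation),
                               locator = locator)
    fld <- solve_fem(sys, "gmres", tol = tol, max_iter = max_iter,
                     preconditioner = preconditioner)
    phi <- evaluate_field(fld, pts, locator = locator)
    psi <- dipole_potential(model, pos, current * separation * u, pts)
    ## the analytic series has no potential reference constraint; compare
    ## after removing the mean offset implied by the finite domain
    rd <- relative_difference(phi - mean(phi), psi - mean(psi))
    if (verbose)
      message(sprintf("depth %.1f mm %-10s RD = %.4f (%d iters)",
                      d * 1e3, o, rd, fld$info$iterations))
    res <- rbind(res, data.frame(depth = d, orientation = o, rd = rd))
  }
  if (!is.null(out_csv)) write.csv(res, out_csv, row.names = FALSE)
  res
}
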