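## Krylov solution of the assembled systems. Real SPD systems may use
## preconditioned CG (with constant-nullspace deflation for pure-Neumann
## problems); complex-block and floating-electrode systems are solved
## with right-preconditioned restarted GMRES on the bordered operator.
## The zero-mean potential reference (int_Omega phi dx = 0) is imposed as
## a Lagrange row on the GMRES path and by deflation + mean shift on the
## CG path (the two give the same field for consistent sources); it is
## omitted as soon as a Robin electrode makes the operator nonsingular.

## assemble the bordered operator and rhs for a fem_system
.build_operator <- function(system) {
  n <- system$dofinfo$ndof
  cplx <- system$mode == "complex_block"
  floats <- Filter(function(e) e$role == "recording", system$electrodes)
  if (any(vapply(floats, function(e) is.na(e$float_index), logical(1))))
    stop("recording electrode without add_floating_electrode")
  nfl <- length(floats)
  zm <- !system$has_robin
  stride <- if (cplx) 2L else 1L
  ntot <- stride * (n + nfl + as.integer(zm))

  tr_i <- list(); tr_j <- list(); tr_x <- list()
  push <- function(i, j, x) {
    k <- length(tr_i) + 1L
    tr_i[[k]] <<- as.integer(i); tr_j[[k]] <<- as.integer(j)
    tr_x[[k]] <<- as.numeric(x)
  }
  Ar <- as(system$A_r, "TsparseMatrix")
  push(Ar@i + 1L, Ar@j + 1L, Ar@x)
  if (cplx) {
    push(n + Ar@i + 1L, n + Ar@j + 1L, Ar@x)
    Ai <- as(system$A_i, "TsparseMatrix")
    if (length(Ai@x)) {
      push(Ai@i + 1L, n + Ai@j + 1L, -Ai@x)
      push(n + Ai@i + 1L, Ai@j + 1L, Ai@x)
    }
  }
  base_fl <- stride * n
  for (e in floats) {
    nz <- which(e$m != 0)
    mi <- e$m[nz]
    g <- Re(e$y); b <- Im(e$y)
    if (!cplx) {
      cfl <- base_fl + e$float_index
      push(nz, rep(cfl, length(nz)), -g * mi)           # Robin phi_metal col
      push(rep(cfl, length(nz)), nz, mi / e$S)          # surface-average row
      push(cfl, cfl, -1)
    } else {
      cr <- base_fl + 2L * (e$float_index - 1L) + 1L
      ci <- cr + 1L
      push(nz, rep(cr, length(nz)), -g * mi)
      push(nz, rep(ci, length(nz)), b * mi)
      push(n + nz, rep(ci, length(nz)), -g * mi)
      push(n + nz, rep(cr, length(nz)), -b * mi)
      push(rep(cr, length(nz)), nz, mi / e$S)
      push(cr, cr, -1)
      push(rep(ci, length(nz)), n + nz, mi / e$S)
      push(ci, ci, -1)
    }
  }
  if (zm) {
    w <- system$vol_weights
    zr <- stride * (n + nfl) + 1L
    push(rep(zr, n), 1:n, w); push(1:n, rep(zr, n), w)
    if (cplx) {
      zi <- zr + 1L
      push(rep(zi, n), n + 1:n, w); push(n + 1:n, rep(zi, n), w)
    }
  }
  A <- Matrix::sparseMatrix(i = unlist(tr_i), j = unlist(tr_j),
                            x = unlist(tr_x), dims = c(ntot, ntot))
  rhs <- numeric(ntot)
  rhs[1:n] <- system$b_r
  if (cplx) rhs[n + 1:n] <- system$b_i
  list(A = A, rhs = rhs, n = n, nfl = nfl, zm = zm, stride = stride,
       floats = floats, ntot = ntot)
}

## preconditioners return a function z = M^{-1} r
.make_precond <- function(system, op, preconditioner) {
  n <- op$n; ntot <- op$ntot; stride <- op$stride
  if (is.function(preconditioner)) return(preconditioner)
  if (preconditioner == "none") return(identity)
  if (preconditioner == "jacobi") {
    d <- Matrix::diag(op$A)
    d[d == 0] <- 1
    d[abs(d) < 1e-300] <- 1
    return(function(r) r / d)
  }
  if (preconditioner == "chol") {
    P <- system$A_r
    if (!system$has_robin) {
      ## pin one dof so the Neumann operator factors; the preconditioner
      ## need not be exact
      sc <- mean(Matrix::diag(P))
      P <- P + Matrix::sparseMatrix(i = 1L, j = 1L, x = sc,
                                    dims = dim(P))
    }
    fac <- Matrix::Cholesky(Matrix::forceSymmetric(P), LDL = FALSE,
                            perm = TRUE)
    return(function(r) {
      z <- r
      z[1:n] <- as.numeric(Matrix::solve(fac, r[1:n], system = "A"))
      if (stride == 2L)
        z[n + 1:n] <- as.numeric(Matrix::solve(fac, r[n + 1:n],
                                               system = "A"))
      z
    })
  }
  stop("unknown preconditioner: ", preconditioner)
}

## deflated preconditioned CG for (possibly singular, consistent) SPD A
.pcg <- function(Afun, b, Mfun, tol, max_iter, deflate = FALSE) {
  n <- length(b)
  proj <- if (deflate) function(v) v - sum(v) / n else identity
  b <- proj(b)
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(list(x = numeric(n), iter = 0L, relres = 0,
                           history = numeric(0)))
  x <- numeric(n)
  r <- b
  z <- proj(Mfun(r))
  p <- z
  rz <- sum(r * z)
  hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    Ap <- Afun(p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    relres <- sqrt(sum(r^2)) / nb
    hist <- c(hist, relres)
    if (relres <= tol)
      return(list(x = x, iter = it, relres = relres, history = hist))
    z <- proj(Mfun(r))
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  stop(sprintf(
    "CG did not converge in %d iterations (relative residual %.3e); %s",
    max_iter, hist[length(hist)],
    paste("history tail:", paste(sprintf("%.2e", tail(hist, 5)),
                                 collapse = " "))))
}

## right-preconditioned restarted GMRES
.gmres <- function(Afun, b, Mfun, tol, max_iter, restart = 100L) {
  n <- length(b)
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(list(x = numeric(n), iter = 0L, relres = 0,
                           history = numeric(0)))
  x <- numeric(n)
  hist <- numeric(0)
  total <- 0L
  repeat {
    r <- b - Afun(x)
    beta <- sqrt(sum(r^2))
    if (beta / nb <= tol)
      return(list(x = x, iter = total, relres = beta / nb, history = hist))
    m <- min(restart, max_iter - total)
    if (m <= 0L) break
    V <- matrix(0, n, m + 1L)
    H <- matrix(0, m + 1L, m)
    cs <- sn <- numeric(m)
    g <- numeric(m + 1L); g[1] <- beta
    V[, 1] <- r / beta
    k_used <- 0L
    for (k in seq_len(m)) {
      w <- Afun(Mfun(V[, k]))
      for (i in seq_len(k)) {
        H[i, k] <- sum(w * V[, i])
        w <- w - H[i, k] * V[, i]
      }
      H[k + 1L, k] <- sqrt(sum(w^2))
      if (H[k + 1L, k] > 1e-300) V[, k + 1L] <- w / H[k + 1L, k]
      ## apply accumulated Givens rotations
      for (i in seq_len(k - 1L)) {
        t1 <- cs[i] * H[i, k] + sn[i] * H[i + 1L, k]
        H[i + 1L, k] <- -sn[i] * H[i, k] + cs[i] * H[i + 1L, k]
        H[i, k] <- t1
      }
      d <- sqrt(H[k, k]^2 + H[k + 1L, k]^2)
      cs[k] <- H[k, k] / d; sn[k] <- H[k + 1L, k] / d
      H[k, k] <- d; H[k + 1L, k] <- 0
      g[k + 1L] <- -sn[k] * g[k]
      g[k] <- cs[k] * g[k]
      total <- total + 1L
      relres <- abs(g[k + 1L]) / nb
      hist <- c(hist, relres)
      k_used <- k
      if (relres <= tol || total >= max_iter) break
    }
    y <- backsolve(H[seq_len(k_used), seq_len(k_used), drop = FALSE],
                   g[seq_len(k_used)])
    x <- x + Mfun(as.numeric(V[, seq_len(k_used), drop = FALSE] %*% y))
    if (hist[length(hist)] <= tol)
      return(list(x = as.numeric(x), iter = total,
                  relres = hist[length(hist)], history = hist))
    if (total >= max_iter) break
  }
  stop(sprintf(
    "GMRES did not converge in %d iterations (relative residual %.3e); history tail: %s",
    total, hist[length(hist)],
    paste(sprintf("%.2e", tail(hist, 5)), collapse = " ")))
}

#' Solve an assembled FEM system
#'
#' @param system a `fem_system` (after assembly, electrodes, sources).
#' @param method `"cg"` or `"gmres"`. Complex-block systems and systems
#'   with floating electrodes are not symmetric positive definite and must
#'   use `"gmres"` (enforced with an error).
#' @param tol relative residual tolerance (default 1e-8).
#' @param max_iter iteration cap.
#' @param preconditioner `"jacobi"` (default), `"none"`, `"chol"`
#'   (CHOLMOD factorization of the real stiffness part, recommended for
#'   large complex-block solves), or a function `r -> z`.
#' @param restart GMRES restart length.
#' @return object of class `potential_field`: `values` (numeric or complex
#'   dof vector; for pure-Neumann problems referenced to zero volume
#'   mean), `phi_metal` (named complex vector of floating-electrode
#'   potentials), `mesh`, `dofinfo`, `info` (iterations, relative
#'   residual, history).
#' @export
solve_fem <- function(system, method = c("gmres", "cg"), tol = 1e-8,
                      max_iter = 2000L, preconditioner = "jacobi",
                      restart = 100L) {
  method <- match.arg(method)
  if (system$mode == "complex_block" && method == "cg")
    stop("complex_block systems must be solved with GMRES ",
         "(the real block operator is not symmetric positive definite)")
  op <- .build_operator(system)
  if (method == "cg" && op$nfl > 0L)
    stop("floating electrodes make the operator unsymmetric; use GMRES")
  n <- op$n
  if (method == "cg") {
    ## solve on the unbordered SPD block, with nullspace deflation when
    ## pure Neumann; then shift to the zero volume-mean reference
    A <- system$A_r
    Afun <- function(x) as.numeric(A %*% x)
    Mn <- if (is.function(preconditioner)) {
      preconditioner
    } else if (preconditioner == "none") {
      identity
    } else if (preconditioner == "jacobi") {
      d <- Matrix::diag(A); d[d == 0] <- 1
      function(r) r / d
    } else if (preconditioner == "chol") {
      P <- A
      if (op$zm) {
        sc <- mean(Matrix::diag(P))
        P <- P + Matrix::sparseMatrix(i = 1L, j = 1L, x = sc, dims = dim(P))
      }
      fac <- Matrix::Cholesky(Matrix::forceSymmetric(P), LDL = FALSE,
                              perm = TRUE)
      function(r) as.numeric(Matrix::solve(fac, r, system = "A"))
    } else stop("unknown preconditioner: ", preconditioner)
    res <- .pcg(Afun, system$b_r[1:n], Mn, tol, max_iter,
                deflate = op$zm)
    x <- res$x
    if (op$zm) {
      w <- system$vol_weights
      x <- x - sum(w * x) / sum(w)
    }
    values <- x
    phi_metal <- complex(0)
    lambda <- numeric(0)
  } else {
    Mfun <- .make_precond(system, op, preconditioner)
    Afull <- op$A
    Afun <- function(x) as.numeric(Afull %*% x)
    res <- .gmres(Afun, op$rhs, Mfun, tol, max_iter, restart)
    x <- res$x
    if (system$mode == "complex_block") {
      values <- complex(real = x[1:n], imaginary = x[n + 1:n])
      base_fl <- 2L * n
      phi_metal <- complex(0)
      for (e in op$floats) {
        cr <- base_fl + 2L * (e$float_index - 1L) + 1L
        phi_metal <- c(phi_metal, setNames(
          complex(real = x[cr], imaginary = x[cr + 1L]),
          as.character(e$marker)))
      }
    } else {
      values <- x[1:n]
      phi_metal <- complex(0)
      for (e in op$floats) {
        phi_metal <- c(phi_metal, setNames(
          complex(real = x[n + e$float_index], imaginary = 0),
          as.character(e$marker)))
      }
    }
    lambda <- if (op$zm) tail(x, op$stride) else numeric(0)
  }
  structure(list(values = values, phi_metal = phi_metal, lambda = lambda,
                 mesh = system$mesh, dofinfo = system$dofinfo,
                 mode = system$mode,
                 info = list(iterations = res$iter, relres = res$relres,
                             history = res$history, method = method)),
            class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("potential_field: %d dofs (%s, order %d), %s in %d iterations (relres %.2e)\n",
              length(x$values), x$mode, x$dofinfo$order, x$info$method,
              x$info$iterations, x$info$relres))
  if (length(x$phi_metal))
    cat("  phi_metal:", paste(names(x$phi_metal),
                              format(x$phi_metal, digits = 4),
                              sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Evaluate a potential field at points
#'
#' Barycentric (P1) or quadratic (P2) interpolation inside the containing
#' cell of each point.
#'
#' @param field a `potential_field` (or a bare dof vector together with
#'   `system`).
#' @param points `n` x 3 matrix.
#' @param locator optional prebuilt [mesh_locator()].
#' @param nearest passed to [locate_points()]: allow nearest-cell
#'   evaluation for points marginally outside the mesh.
#' @return numeric or complex vector of interpolated values.
#' @export
evaluate_field <- function(field, points, locator = NULL, nearest = FALSE) {
  stopifnot(inherits(field, "potential_field"))
  if (is.null(locator)) locator <- mesh_locator(field$mesh)
  loc <- locate_points(locator, points, nearest = nearest)
  pts <- matrix(as.numeric(points), ncol = 3L)
  u <- field$values
  out <- if (is.complex(u)) complex(nrow(pts)) else numeric(nrow(pts))
  tets <- field$mesh$tets
  if (field$dofinfo$order == 1L) {
    for (k in 1:4)
      out <- out + u[tets[loc$cell, k]] * loc$bary[, k]
  } else {
    dof_e <- field$dofinfo$cell_edges
    nn <- field$dofinfo$nn
    l <- loc$bary
    for (k in 1:4)
      out <- out + u[tets[loc$cell, k]] * l[, k] * (2 * l[, k] - 1)
    for (e in 1:6) {
      a <- .tet_epairs[e, 1]; b <- .tet_epairs[e, 2]
      out <- out + u[nn + dof_e[loc$cell, e]] * 4 * l[, a] * l[, b]
    }
  }
  out
}

#' Interface currents of all Robin electrodes (Kirchhoff check)
#'
#' Current delivered from the metal into the tissue,
#' `I_k = int_Gamma_k y_k (phi_metal_k - phi) ds = y_k (phi_metal_k S_k -
#' m' u)`; without internal sources the currents across all electrodes
#' must sum to zero (up to solver tolerance).
#'
#' @param system the solved `fem_system`.
#' @param field the corresponding `potential_field`.
#' @return named complex vector of per-electrode currents (A), names =
#'   facet markers.
#' @export
interface_currents <- function(system, field) {
  out <- complex(0)
  u <- field$values
  for (e in system$electrodes) {
    pm <- if (e$role == "recording")
      field$phi_metal[[as.character(e$marker)]]
    else as.complex(e$phi_metal)
    I <- e$y * (pm * e$S - sum(e$m * u))
    out <- c(out, setNames(I, as.character(e$marker)))
  }
  out
}

#' Volume-weighted mean of a potential field
#'
#' `(int_Omega phi dx) / |Omega|`; the zero-mean reference drives this to
#' zero for pure-Neumann solves.
#'
#' @param field a `potential_field`.
#' @param system the `fem_system` it came from.
#' @return scalar (complex in block mode).
#' @export
field_volume_mean <- function(field, system) {
  w <- system$vol_weights
  sum(w * field$values) / sum(w)
}
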