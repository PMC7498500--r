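test_that("P1 stiffness matches hand formula and dense oracle", {
  ## reference tet: K = V sigma G'G with G the barycentric gradients
  s1 <- assemble_stiffness(unit_tet_mesh(), list("1" = 1))
  G <- rbind(c(-1, -1, -1), diag(3))
  K <- (1 / 6) * G %*% t(G)
  expect_lt(max(abs(as.matrix(s1$A_r) - K)), 1e-14)
  expect_lt(max(abs(rowSums(as.matrix(s1$A_r)))), 1e-14)

  ## two-tet mesh, mixed markers, against the independent dense assembler
  m2 <- two_tet_mesh(c(1L, 2L))
  mat <- list("1" = 0.7, "2" = 1.9)
  s2 <- assemble_stiffness(m2, mat)
  expect_lt(max(abs(as.matrix(s2$A_r) - dense_stiffness_oracle(m2, mat))),
            1e-14)

  ## tensor conductivity
  Tn <- anisotropic_tensor(2.2, 0.6, c(1, 1, 0))
  mats <- list("1" = Tn, "2" = Tn)
  st <- assemble_stiffness(m2, mats)
  expect_lt(max(abs(as.matrix(st$A_r) - dense_stiffness_oracle(m2, mats))),
            1e-13)

  ## constants in the nullspace on a real mesh
  mesh <- ball_mesh()
  sys <- assemble_stiffness(mesh, list("1" = 0.33))
  expect_lt(max(abs(sys$A_r %*% rep(1, nrow(mesh$nodes)))), 1e-12)

  ## unmapped marker is named in the error
  expect_error(assemble_stiffness(m2, list("1" = 1)), "2")
})

test_that("complex block solve equals dense complex oracle on small meshes", {
  mesh <- ball_mesh(0.05, 0.05)   # << 300 dofs
  n <- nrow(mesh$nodes)
  expect_lt(n, 300L)
  y <- complex(real = 0.3, imaginary = 0.11)
  src <- dipole_source(c(0, 0, 0.02), c(1, 0, 1) / sqrt(2))
  sys <- assemble_complex_block(mesh, list("1" = y))
  sys <- assemble_source_rhs(sys, src)
  fld <- solve_fem(sys, "gmres", tol = 1e-13, preconditioner = "chol",
                   max_iter = 3000L)
  ## dense oracle: native complex matrix with a zero-mean Lagrange row
  Ad <- as.matrix(sys$A_r) + 1i * as.matrix(sys$A_i)
  w <- sys$vol_weights
  sol <- solve(rbind(cbind(Ad, w), c(w, 0)),
               c(sys$b_r + 1i * sys$b_i, 0))
  expect_lt(max(Mod(fld$values - sol[1:n])) / max(Mod(sol[1:n])), 1e-10)

  ## y_i = 0: block solve equals the real solve, imaginary part zero
  sys0 <- assemble_complex_block(mesh, list("1" = 0.3 + 0i))
  sys0 <- assemble_source_rhs(sys0, src)
  f0 <- solve_fem(sys0, "gmres", tol = 1e-12, preconditioner = "chol",
                  max_iter = 3000L)
  sysr <- assemble_stiffness(mesh, list("1" = 0.3))
  sysr <- assemble_source_rhs(sysr, src)
  fr <- solve_fem(sysr, "cg", tol = 1e-12, preconditioner = "chol")
  expect_lt(max(abs(Im(f0$values))) / max(abs(Re(f0$values))), 1e-9)
  expect_lt(max(abs(Re(f0$values) - fr$values)) / max(abs(fr$values)),
            1e-9)

  ## conjugating the admittivity conjugates the solution (real source)
  sysc <- assemble_complex_block(mesh, list("1" = Conj(y)))
  sysc <- assemble_source_rhs(sysc, src)
  fc <- solve_fem(sysc, "gmres", tol = 1e-13, preconditioner = "chol",
                  max_iter = 3000L)
  expect_lt(max(Mod(fc$values - Conj(fld$values))) / max(Mod(fld$values)),
            1e-9)
})

test_that("Robin interfaces: no-op at y = 0, Dirichlet limit, series circuit", {
  m <- column_mesh()
  sigma <- 1.2
  mat <- list("1" = sigma, "2" = sigma)
  sys0 <- assemble_stiffness(m, mat)
  ## y = 0 leaves operator and rhs untouched
  sz <- add_robin_interface(sys0,
    electrode_spec(201L, "stimulating", interface = 0 + 0i,
                   phi_metal = 1), 0)
  expect_lt(max(abs(sz$A_r - sys0$A_r)), 1e-300)
  expect_identical(sz$b_r, sys0$b_r)

  g1 <- 5e3; g2 <- 8e3
  sys <- assemble_stiffness(m, mat)
  sys <- add_robin_interface(sys,
    electrode_spec(201L, "stimulating", interface = g1 + 0i,
                   phi_metal = 1), 0)
  sys <- add_robin_interface(sys,
    electrode_spec(202L, "ground", interface = g2 + 0i), 0)
  fld <- solve_fem(sys, "cg", tol = 1e-12, preconditioner = "chol")
  I <- interface_currents(sys, fld)
  ## Kirchhoff across all electrodes
  expect_kirchhoff(sys, fld, 1e-6)
  ## 1-D series circuit: R_int1 + R_bulk + R_int2
  A <- (4e-3)^2; L <- 8e-3
  Rtot <- 1 / (g1 * A) + L / (sigma * A) + 1 / (g2 * A)
  expect_lt(abs(Re(I[["201"]]) * Rtot - 1), 0.02)

  ## g -> infinity approaches a Dirichlet patch
  sysd <- assemble_stiffness(m, mat)
  sysd <- add_robin_interface(sysd,
    electrode_spec(201L, "stimulating", interface = 1e12 + 0i,
                   phi_metal = 0.5), 0)
  sysd <- add_robin_interface(sysd,
    electrode_spec(202L, "ground", interface = g2 + 0i), 0)
  fd <- solve_fem(sysd, "cg", tol = 1e-12, preconditioner = "chol")
  bot <- which(abs(m$nodes[, 3]) < 1e-12)
  expect_lt(max(abs(fd$values[bot] - 0.5)) / 0.5, 1e-4)
})

test_that("floating electrodes satisfy the surface-average constraint", {
  ## column driven to a linear field in z; recording patches on the side
  ## walls
  m <- column_mesh(a = 4e-3, L = 8e-3, h = 1e-3)
  bc <- (m$nodes[m$facets[, 1], ] + m$nodes[m$facets[, 2], ] +
         m$nodes[m$facets[, 3], ]) / 3
  zlo <- 3e-3; zhi <- 5e-3
  sel1 <- abs(bc[, 2] + 2e-3) < 1e-12 & bc[, 3] > zlo & bc[, 3] < zhi
  sel2 <- abs(bc[, 2] - 2e-3) < 1e-12 & bc[, 3] > zlo & bc[, 3] < zhi
  expect_true(any(sel1) && any(sel2))
  m$facet_markers[sel1] <- 301L
  m$facet_markers[sel2] <- 302L
  sys <- assemble_stiffness(m, list("1" = 1, "2" = 1))
  sys <- add_robin_interface(sys,
    electrode_spec(201L, "ground", interface = 1e9 + 0i), 0)
  sys <- add_robin_interface(sys,
    electrode_spec(202L, "stimulating", interface = 1e9 + 0i,
                   phi_metal = 1), 0)
  e1 <- electrode_spec(301L, "recording", interface = 20 + 0i)
  e2 <- electrode_spec(302L, "recording", interface = 20 + 0i)
  sys <- add_robin_interface(sys, e1, 0)
  ## solving before add_floating_electrode is an error
  expect_error(solve_fem(sys, "gmres", preconditioner = "chol"),
               "add_floating_electrode")
  sys <- add_floating_electrode(sys, e1, 0)
  sys <- add_robin_interface(sys, e2, 0)
  sys <- add_floating_electrode(sys, e2, 0)
  expect_error(solve_fem(sys, "cg", preconditioner = "chol"), "GMRES")
  fld <- solve_fem(sys, "gmres", tol = 1e-12, preconditioner = "chol",
                   max_iter = 3000L)
  ## constraint residual: phi_metal equals the area-weighted mean
  for (e in Filter(function(e) e$role == "recording", sys$electrodes)) {
    pm <- fld$phi_metal[[as.character(e$marker)]]
    expect_lt(Mod(pm - sum(e$m * fld$values) / e$S),
              1e-10 * max(Mod(fld$values)))
  }
  ## linear field: phi_metal matches the patch centroid potential z/L
  zc <- (zlo + zhi) / 2
  expect_lt(abs(Re(fld$phi_metal[["301"]]) - zc / 8e-3) / (zc / 8e-3),
            0.01)
  ## symmetry: the two opposite patches read the same value (up to the
  ## Krylov solver tolerance)
  expect_lt(Mod(fld$phi_metal[["301"]] - fld$phi_metal[["302"]]),
            1e-4 * Mod(fld$phi_metal[["301"]]))
  ## a floating electrode draws no net current under the surface-average
  ## constraint
  I <- interface_currents(sys, fld)
  expect_lt(Mod(I[["301"]]) / Mod(I[["201"]]), 1e-9)
})

test_that("point sources distribute by basis evaluation", {
  mesh <- ball_mesh()
  sys <- assemble_stiffness(mesh, list("1" = 1))
  ## a non-balanced monopole in a pure-Neumann problem warns
  nid <- 17L
  expect_warning(assemble_source_rhs(sys,
    source_spec(mesh$nodes[nid, , drop = FALSE], 3e-6)), "sum to zero")
  ## monopole exactly at a node
  sysn <- suppressWarnings(assemble_source_rhs(sys,
    source_spec(mesh$nodes[nid, , drop = FALSE], 3e-6)))
  expect_equal(sysn$b_r[nid], 3e-6, tolerance = 1e-12)
  expect_lt(sum(abs(sysn$b_r[-nid])), 1e-18)
  ## monopole at a cell centroid: four entries of I/4
  ctd <- cell_centroids(mesh)[100, , drop = FALSE]
  sysc <- suppressWarnings(assemble_source_rhs(sys, source_spec(ctd, 8e-6)))
  nz <- which(sysc$b_r != 0)
  expect_identical(sort(nz), sort(mesh$tets[100, ]))
  expect_equal(unname(sysc$b_r[nz]), rep(2e-6, 4), tolerance = 1e-12)
  ## dipole rhs sums to zero
  sysd <- assemble_source_rhs(sys, dipole_source(c(0, 0, 0.02), c(1, 0, 0)))
  expect_lt(abs(sum(sysd$b_r)), 1e-18)
  ## outside point errors with the location
  expect_error(suppressWarnings(assemble_source_rhs(sys,
    source_spec(c(1, 0, 0), 1e-6))), "outside")
})

test_that("solver contracts: cg/gmres agreement, reference, enforcement", {
  mesh <- ball_mesh(0.05, 0.015)
  sys <- assemble_stiffness(mesh, list("1" = 0.33))
  sys <- assemble_source_rhs(sys, dipole_source(c(0, 0, 0.02), c(0, 0, 1)))
  f1 <- solve_fem(sys, "cg", tol = 1e-10, preconditioner = "jacobi",
                  max_iter = 5000L)
  f2 <- solve_fem(sys, "gmres", tol = 1e-10, preconditioner = "chol",
                  max_iter = 3000L)
  expect_lt(max(abs(f1$values - f2$values)) / max(abs(f1$values)), 1e-7)
  ## zero volume-mean reference on both paths
  expect_lt(abs(field_volume_mean(f1, sys)), 1e-10 * max(abs(f1$values)))
  expect_lt(abs(field_volume_mean(f2, sys)), 1e-10 * max(abs(f2$values)))
  ## complex block + cg is rejected
  sysc <- assemble_complex_block(mesh, list("1" = 0.3 + 0.1i))
  expect_error(solve_fem(sysc, "cg"), "GMRES")
  ## non-convergence raises with iteration count and residual history
  expect_error(solve_fem(sys, "cg", tol = 1e-14, max_iter = 3L,
                         preconditioner = "none"), "3 iterations")
})

test_that("field evaluation: nodal values, linear exactness, random points", {
  mesh <- ball_mesh()
  sys <- assemble_stiffness(mesh, list("1" = 1))
  lin <- function(x) 0.3 + 2 * x[, 1] - x[, 2] + 0.5 * x[, 3]
  fld <- structure(list(values = lin(mesh$nodes), mesh = mesh,
                        dofinfo = sys$dofinfo, mode = "real"),
                   class = "potential_field")
  ## nodal evaluation returns nodal values
  ids <- c(1L, 5L, 40L)
  expect_equal(evaluate_field(fld, mesh$nodes[ids, , drop = FALSE]),
               fld$values[ids], tolerance = 1e-12)
  ## P1 reproduces linear fields exactly at random interior points
  set.seed(7)
  p <- matrix(rnorm(300), ncol = 3)
  p <- p / sqrt(rowSums(p^2)) * runif(100, 0, 0.045)
  expect_equal(evaluate_field(fld, p), lin(p), tolerance = 1e-10)
  expect_error(evaluate_field(fld, rbind(c(1, 1, 1))), "outside")
})

test_that("P2 elements: nullspace, quadratic interpolation, linear solve", {
  mesh <- ball_mesh(0.05, 0.025)
  sys2 <- assemble_stiffness(mesh, list("1" = 0.8), order = 2L)
  expect_lt(max(abs(sys2$A_r %*% rep(1, sys2$dofinfo$ndof))), 1e-12)
  ## quadratic fields are interpolated exactly by the P2 basis
  qf <- function(x) 1 + x[, 1] + 2 * x[, 2] * x[, 3] + x[, 1]^2
  ue <- sys2$dofinfo$ue
  mids <- (mesh$nodes[ue$edges[, 1], ] + mesh$nodes[ue$edges[, 2], ]) / 2
  vals <- c(qf(mesh$nodes), qf(mids))
  fld <- structure(list(values = vals, mesh = mesh,
                        dofinfo = sys2$dofinfo, mode = "real"),
                   class = "potential_field")
  set.seed(8)
  p <- matrix(rnorm(150), ncol = 3)
  p <- p / sqrt(rowSums(p^2)) * runif(50, 0, 0.045)
  expect_equal(evaluate_field(fld, p), qf(p), tolerance = 1e-10)
  ## P2 column solve reproduces the linear ramp exactly
  m <- column_mesh(a = 4e-3, L = 8e-3, h = 2e-3)
  sys <- assemble_stiffness(m, list("1" = 1, "2" = 1), order = 2L)
  sys <- add_robin_interface(sys,
    electrode_spec(201L, "ground", interface = 1e10 + 0i), 0)
  sys <- add_robin_interface(sys,
    electrode_spec(202L, "stimulating", interface = 1e10 + 0i,
                   phi_metal = 1), 0)
  fld2 <- solve_fem(sys, "cg", tol = 1e-12, preconditioner = "chol")
  pts <- cbind(0, 0, c(1e-3, 3e-3, 6.5e-3))
  expect_equal(Re(evaluate_field(fld2, pts)), pts[, 3] / 8e-3,
               tolerance = 1e-6)
})
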