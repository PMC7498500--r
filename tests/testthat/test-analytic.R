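test_that("layered series matches the infinite-medium dipole far from the boundary", {
  set.seed(3)
  y <- complex(real = 0.3, imaginary = 0.05)
  pos <- c(0.01, -0.02, 0.05)
  mom <- c(2e-8, -1e-8, 3e-8)
  pts <- matrix(rnorm(30), 10, 3)
  pts <- pts / sqrt(rowSums(pts^2)) * runif(10, 0.07, 0.08)
  big <- four_sphere_model(10, y, n_terms = 300)  # boundary 10 m away
  v <- dipole_potential(big, pos, mom, pts)
  d <- sweep(pts, 2, pos)
  exact <- (d %*% mom)[, 1] / (4 * pi * y * sqrt(rowSums(d^2))^3)
  expect_lt(max(Mod(v - exact)) / max(Mod(exact)), 1e-5)
})

test_that("equal admittivities reduce to the homogeneous-sphere closed form", {
  set.seed(4)
  y <- complex(real = 0.25, imaginary = 0.08)
  pos <- c(0.005, 0.01, 0.07)
  mom <- c(1e-7, 5e-8, -2e-8)
  pts <- matrix(rnorm(60), 20, 3)
  pts <- pts / sqrt(rowSums(pts^2)) * runif(20, 0.05, 0.0899)
  m4 <- four_sphere_model(head_radii, rep(y, 4), n_terms = 1000)
  v4 <- dipole_potential(m4, pos, mom, pts)
  oracle <- femvc:::homogeneous_sphere_dipole(0.09, y, pos, mom, pts, 1000)
  expect_lt(max(Mod(v4 - oracle)) / max(Mod(oracle)), 1e-8)
})

test_that("series symmetry, linearity and error handling", {
  ys <- complex(real = c(0.3, 2, 0.04, 0.2),
                imaginary = c(0.17, 0.06, 0.02, 0.2))
  m4 <- four_sphere_model(head_radii, ys)
  ## rotational symmetry of a radial dipole about its axis
  th <- 0.7; phis <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- 0.079 * cbind(sin(th) * cos(phis), sin(th) * sin(phis),
                        rep(cos(th), 12))
  vr <- dipole_potential(m4, c(0, 0, 0.074), c(0, 0, 1e-7), ring)
  expect_lt(max(Mod(vr - vr[1])), 1e-12 * max(Mod(vr)))
  ## linearity in the moment
  pts <- surface_sample_points(0.079, 50)
  a <- dipole_potential(m4, c(0, 0, 0.07), c(1e-7, 0, 2e-8), pts)
  b <- dipole_potential(m4, c(0, 0, 0.07), 3.7 * c(1e-7, 0, 2e-8), pts)
  expect_lt(max(Mod(b - 3.7 * a)) / max(Mod(b)), 1e-12)
  ## dipole outside the innermost layer is rejected
  expect_error(dipole_potential(m4, c(0, 0, 0.0795), c(0, 0, 1e-7), pts),
               "innermost")
})

test_that("series truncation error decays geometrically with depth", {
  ## the tail of the series decays like (r_dipole / r_1)^n, so truncation
  ## at 500 terms leaves ~3e-5 at 1 mm depth, 5e-8 at 2 mm, < 1e-10 at
  ## 3 mm and deeper
  ys <- complex(real = c(0.3, 2, 0.04, 0.2),
                imaginary = c(0.17, 0.06, 0.02, 0.2))
  pts <- surface_sample_points(0.079, 500)
  bound <- c("1" = 1e-4, "2" = 1e-6, "3" = 1e-9, "5" = 1e-12)
  m500 <- four_sphere_model(head_radii, ys, 500)
  m1000 <- four_sphere_model(head_radii, ys, 1000)
  rds <- numeric(0)
  for (depth_mm in c(1, 2, 3, 5)) {
    pos <- c(0, 0, 0.079 - depth_mm * 1e-3)
    a <- dipole_potential(m500, pos, c(1e-7, 0, 0), pts)
    b <- dipole_potential(m1000, pos, c(1e-7, 0, 0), pts)
    rd <- relative_difference(a, b)
    expect_lt(rd, bound[[as.character(depth_mm)]])
    rds <- c(rds, rd)
  }
  expect_true(all(diff(rds) < 0))
})

test_that("relative difference formula", {
  x <- rnorm(40)
  expect_identical(relative_difference(x, x), 0)
  psi <- rep(2 + 0i, 25)
  phi <- psi + (0.3 - 0.1i)
  expect_equal(relative_difference(phi, psi), Mod(0.3 - 0.1i) / 2,
               tolerance = 1e-14)
  expect_error(relative_difference(phi, rep(0, 25)), "zero")
  expect_error(relative_difference(1:3, 1:4), "length")
})

test_that("validate_study1 returns the RD sweep with the expected structure", {
  mesh <- head_mesh_coarse(0.012)
  ys <- vapply(c("grey", "csf", "skull", "scalp"),
               function(t) tissue_admittivity(t, 1e7)$value, complex(1))
  res <- validate_study1(mesh, head_radii, ys,
                         depths = c(2e-3, 5e-3),
                         orientations = c("tangential", "radial"),
                         n_points = 400L, tol = 1e-8,
                         preconditioner = "chol")
  expect_identical(nrow(res), 4L)
  expect_identical(sort(unique(res$orientation)),
                   c("radial", "tangential"))
  expect_true(all(res$rd > 0 & res$rd < 0.5))
  ## deeper dipoles have smaller or equal RD (10% slack)
  for (o in c("tangential", "radial")) {
    r2 <- res$rd[res$depth == 2e-3 & res$orientation == o]
    r5 <- res$rd[res$depth == 5e-3 & res$orientation == o]
    expect_lt(r5, r2 * 1.1, label = o)
  }
  ## identical inputs on both sides give RD = 0 (trivial contract)
  model <- four_sphere_model(head_radii, ys)
  pts <- surface_sample_points(0.079, 100)
  psi <- dipole_potential(model, c(0, 0, 0.074), c(1e-7, 0, 0), pts)
  expect_identical(relative_difference(psi, psi), 0)
})
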