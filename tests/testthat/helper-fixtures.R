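## Shared fixtures, all built in code.

unit_tet_mesh <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           rbind(1:4))
}

two_tet_mesh <- function(markers = c(1L, 1L)) {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(1, 1, 1)),
           rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)), markers)
}

## coarse single-ball mesh (~300-2500 tets depending on edge length)
ball_mesh <- function(R = 0.05, el = 0.02) {
  generate_layered_sphere_mesh(sphere_layer_spec(R, edge_length = el))
}

## coarse four-layer head fixture
head_mesh_coarse <- function(el = 0.015) {
  generate_layered_sphere_mesh(
    sphere_layer_spec(c(0.079, 0.080, 0.085, 0.090), edge_length = el))
}

head_radii <- c(0.079, 0.080, 0.085, 0.090)

## independent dense assembly oracle: P1 stiffness via per-cell 4x4
## solves (a different derivation path from the packaged assembler)
dense_stiffness_oracle <- function(mesh, sigma_by_marker) {
  n <- nrow(mesh$nodes)
  A <- matrix(0, n, n)
  for (c in seq_len(nrow(mesh$tets))) {
    vid <- mesh$tets[c, ]
    P <- cbind(1, mesh$nodes[vid, , drop = FALSE])
    C <- solve(P, diag(4))       # basis coefficients: N_i = C[1,i] + C[2:4,i].x
    G <- C[2:4, , drop = FALSE]  # gradients (3 x 4)
    V <- abs(det(P)) / 6
    sig <- sigma_by_marker[[as.character(mesh$cell_markers[c])]]
    if (is.matrix(sig)) Ke <- V * t(G) %*% sig %*% G
    else Ke <- V * sig * (t(G) %*% G)
    A[vid, vid] <- A[vid, vid] + Ke
  }
  A
}

## interior currents balance helper
expect_kirchhoff <- function(system, field, tol = 1e-6) {
  I <- interface_currents(system, field)
  expect_lt(Mod(sum(I)) / max(Mod(I)), tol)
}

## 1-D column fixture: box with whole bottom/top faces remarked as
## electrode patches 201/202
column_mesh <- function(a = 4e-3, L = 8e-3, h = 1e-3) {
  m <- generate_slab_in_bath_mesh(a, L, c(a, a, L / 2), max_cell = h,
                                  ground = FALSE)
  bc <- (m$nodes[m$facets[, 1], ] + m$nodes[m$facets[, 2], ] +
         m$nodes[m$facets[, 3], ]) / 3
  m$facet_markers[abs(bc[, 3]) < 1e-12] <- 201L
  m$facet_markers[abs(bc[, 3] - L) < 1e-12] <- 202L
  m
}
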