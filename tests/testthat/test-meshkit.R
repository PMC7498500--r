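test_that("layered sphere fixture reproduces layer volumes and areas", {
  mesh <- head_mesh_coarse()
  validate_tet_mesh(mesh)
  v <- tet_volumes(mesh)
  bounds <- c(0, head_radii)
  for (k in 1:4) {
    shell <- 4 / 3 * pi * (bounds[k + 1]^3 - bounds[k]^3)
    expect_lt(abs(sum(v[mesh$cell_markers == k]) / shell - 1), 0.02)
  }
  expect_lt(abs(sum(v) / (4 / 3 * pi * 0.09^3) - 1), 0.02)
  ## exterior and brain/CSF interface facet areas
  ext <- mesh$marker_names[["exterior"]]
  expect_lt(abs(sum(facet_areas(mesh, ext)) / (4 * pi * 0.09^2) - 1), 0.02)
  int1 <- mesh$marker_names[["interface_1"]]
  expect_lt(abs(sum(facet_areas(mesh, int1)) / (4 * pi * 0.079^2) - 1),
            0.02)
})

test_that("single-layer ball and determinism contracts", {
  m1 <- ball_mesh()
  expect_true(all(m1$cell_markers == 1L))
  ext <- m1$marker_names[["exterior"]]
  expect_lt(abs(sum(facet_areas(m1, ext)) / (4 * pi * 0.05^2) - 1), 0.02)
  m2 <- ball_mesh()
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tets, m2$tets)
  expect_identical(m1$facet_markers, m2$facet_markers)
  ## sizing guard errors out instead of silently producing garbage
  expect_error(generate_layered_sphere_mesh(
    sphere_layer_spec(0.05, edge_length = 1e-5)), "sizing")
})

test_that("red refinement conserves volume and inherits markers", {
  m <- unit_tet_mesh()
  r <- refine_cells(m, 1L)
  expect_identical(nrow(r$tets), 8L)
  expect_lt(abs(sum(tet_volumes(r)) / sum(tet_volumes(m)) - 1), 1e-14)
  validate_tet_mesh(r)

  mesh <- head_mesh_coarse(0.02)
  pred <- function(x) {
    rr <- sqrt(rowSums(x^2)); rr > 0.070 & rr < 0.082
  }
  ref <- refine_mesh(mesh, pred, min_inradius = 1.5e-3)
  validate_tet_mesh(ref)
  ## exact volume conservation, per marker
  for (k in 1:4)
    expect_lt(abs(sum(tet_volumes(ref)[ref$cell_markers == k]) -
                  sum(tet_volumes(mesh)[mesh$cell_markers == k])),
              1e-15 * sum(tet_volumes(mesh)))
  ## inradius bound met in the region
  sel <- pred(cell_centroids(ref))
  expect_lte(max(tet_inradii(ref)[sel]), 1.5e-3)
  ## conformity: boundary face area equals marked exterior facet area
  ext <- ref$marker_names[["exterior"]]
  bf <- boundary_faces(ref)
  expect_lt(abs(sum(femvc:::triangle_areas(ref$nodes, bf)) -
                sum(facet_areas(ref, ext))), 1e-12)
  ## untouched region stays untouched
  ref2 <- refine_mesh(mesh, function(x) rep(FALSE, nrow(x)), 1e-3)
  expect_identical(ref2$tets, mesh$tets)
})

test_that("slab-in-bath fixture marks patches with exact areas", {
  m <- generate_slab_in_bath_mesh(
    2e-3, 1e-3, c(1e-3, 1e-3, 0.3e-3),
    electrode_patches = list(
      list(shape = "rect", dims = c(60e-6, 250e-6), center = c(0, 0)),
      list(shape = "rect", dims = c(100e-6, 100e-6),
           center = c(350e-6, 0))),
    max_cell = 0.25e-3)
  validate_tet_mesh(m)
  expect_lt(abs(sum(facet_areas(m, 111L)) / 1.5e-8 - 1), 0.02)
  expect_identical(sort(unique(m$facet_markers)),
                   c(101L, 102L, 111L, 112L))
  ## zero patches, no ground: only the exterior marker
  m0 <- generate_slab_in_bath_mesh(2e-3, 1e-3, c(1e-3, 1e-3, 0.3e-3),
                                   ground = FALSE)
  expect_identical(unique(m0$facet_markers), 101L)
  ## overlapping patches are rejected with the offending pair
  expect_error(generate_slab_in_bath_mesh(
    2e-3, 1e-3, c(1e-3, 1e-3, 0.3e-3),
    electrode_patches = list(
      list(shape = "rect", dims = c(200e-6, 200e-6), center = c(0, 0)),
      list(shape = "rect", dims = c(200e-6, 200e-6),
           center = c(100e-6, 0)))), "1 and 2 overlap")
})

test_that("submesh extraction keeps geometry and maps nodes", {
  mesh <- head_mesh_coarse(0.02)
  ## keep everything: identity up to renumbering
  all4 <- extract_submesh(mesh, 1:4)
  expect_equal(nrow(all4$tets), nrow(mesh$tets))
  expect_equal(sum(tet_volumes(all4)), sum(tet_volumes(mesh)),
               tolerance = 1e-14)
  ## innermost ball: cut surface is the r1 sphere
  inner <- extract_submesh(mesh, 1L)
  validate_tet_mesh(inner)
  bf <- boundary_faces(inner)
  expect_lt(abs(sum(femvc:::triangle_areas(inner$nodes, bf)) /
                (4 * pi * 0.079^2) - 1), 0.02)
  nm <- attr(inner, "node_map")
  expect_identical(mesh$nodes[nm, ], inner$nodes)
  ## two-marker two-tet mesh
  tt <- two_tet_mesh(c(1L, 2L))
  one <- extract_submesh(tt, 2L)
  expect_identical(nrow(one$tets), 1L)
  expect_error(extract_submesh(tt, 7L), "not present")
})

test_that("MSH 2.2 round trip is lossless", {
  mesh <- head_mesh_coarse(0.025)
  path <- tempfile(fileext = ".msh")
  write_msh(mesh, path)
  back <- read_msh(path)
  expect_equal(back$nodes, mesh$nodes, tolerance = 1e-15)
  expect_identical(unname(back$tets), unname(mesh$tets))
  expect_identical(back$cell_markers, mesh$cell_markers)
  expect_identical(unname(back$facets), unname(mesh$facets))
  expect_identical(back$facet_markers, mesh$facet_markers)
  expect_identical(back$marker_names[order(names(back$marker_names))],
                   mesh$marker_names[order(names(mesh$marker_names))])
})

test_that("MSH reader rejects non-tet volume cells and reads a minimal file", {
  hexfile <- tempfile(fileext = ".msh")
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$Nodes", "8",
               "1 0 0 0", "2 1 0 0", "3 1 1 0", "4 0 1 0",
               "5 0 0 1", "6 1 0 1", "7 1 1 1", "8 0 1 1",
               "$EndNodes",
               "$Elements", "1",
               "1 5 2 1 1 1 2 3 4 5 6 7 8",
               "$EndElements"), hexfile)
  expect_error(read_msh(hexfile), "hexahedron")
  onetet <- tempfile(fileext = ".msh")
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$Nodes", "4",
               "1 0 0 0", "2 1 0 0", "3 0 1 0", "4 0 0 1",
               "$EndNodes",
               "$Elements", "1",
               "1 4 2 7 7 1 2 3 4",
               "$EndElements"), onetet)
  m <- read_msh(onetet)
  expect_identical(nrow(m$nodes), 4L)
  expect_identical(nrow(m$tets), 1L)
  expect_identical(m$cell_markers, 7L)
})

test_that("surface sample points are on-sphere and quasi-uniform", {
  p1 <- surface_sample_points(0.079, 1)
  expect_equal(sqrt(sum(p1^2)), 0.079, tolerance = 1e-12)
  p <- surface_sample_points(0.079, 2000)
  expect_lt(max(abs(sqrt(rowSums(p^2)) - 0.079)), 1e-12)
  ## nearest-neighbor distance coefficient of variation (n = 1000)
  q <- surface_sample_points(1, 1000)
  d2 <- as.matrix(dist(q))
  diag(d2) <- Inf
  nn <- apply(d2, 1, min)
  expect_lt(sd(nn) / mean(nn), 0.25)
})
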