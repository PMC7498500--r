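## Synthetic fixture generators: layered concentric spheres (head-scale)
## and a slab-in-bath multi-electrode-array stand-in. Both are structured,
## deterministic constructions: no external mesh generator is required.

#' Specification of a layered concentric-sphere mesh
#'
#' @param radii strictly increasing outer radii of the layers, inner to
#'   outer, in meters (layer k occupies the shell between `radii[k-1]` and
#'   `radii[k]`, the innermost layer is a full ball).
#' @param layer_markers integer subdomain ids, one per layer (default
#'   `1:K`).
#' @param edge_length target edge length per layer in meters (scalar or one
#'   value per layer): controls the radial shell spacing within each layer
#'   and the angular resolution (chosen so the outermost requirement is
#'   met).
#' @param refine_region optional `list(center=, radius=, min_inradius=)`
#'   requesting post-generation local refinement inside the given ball
#'   until all cells there have inradius at most `min_inradius`.
#' @return object of class `sphere_layer_spec`.
#' @export
sphere_layer_spec <- function(radii, layer_markers = seq_along(radii),
                              edge_length, refine_region = NULL) {
  radii <- as.numeric(radii)
  if (any(diff(radii) <= 0) || any(radii <= 0))
    stop("radii must be positive and strictly increasing")
  edge_length <- rep_len(as.numeric(edge_length), length(radii))
  if (any(edge_length <= 0)) stop("edge_length must be positive")
  if (!is.null(refine_region)) {
    stopifnot(is.list(refine_region),
              all(c("center", "radius", "min_inradius") %in%
                    names(refine_region)))
    if (refine_region$min_inradius >= min(edge_length))
      stop("refine_region$min_inradius must be smaller than edge_length")
  }
  structure(list(radii = radii, layer_markers = as.integer(layer_markers),
                 edge_length = edge_length, refine_region = refine_region),
            class = "sphere_layer_spec")
}

## unit icosphere: subdivided icosahedron projected to the unit sphere
icosphere <- function(level) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  storage.mode(f) <- "integer"
  for (l in seq_len(level)) {
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    key <- paste(e[, 1], e[, 2])
    keep <- !duplicated(key)
    eu <- e[keep, , drop = FALSE]
    mid <- (v[eu[, 1], , drop = FALSE] + v[eu[, 2], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    midid <- nrow(v) + match(key, key[keep])
    v <- rbind(v, mid)
    nf <- nrow(f)
    m12 <- midid[seq_len(nf)]
    m23 <- midid[nf + seq_len(nf)]
    m31 <- midid[2L * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
    storage.mode(f) <- "integer"
  }
  list(verts = v, faces = f)
}

## Split triangular prisms (bottom a1a2a3, top b1b2b3, columns of `prism`
## = global ids a1 a2 a3 b1 b2 b3) into 3 tets each, choosing quad
## diagonals through the smallest global index so adjacent prisms agree.
split_prisms <- function(prism) {
  n <- nrow(prism)
  perms <- rbind(c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4),
                 c(3, 1, 2, 6, 4, 5), c(4, 6, 5, 1, 3, 2),
                 c(6, 5, 4, 3, 2, 1), c(5, 4, 6, 2, 1, 3))
  wmin <- max.col(-prism, ties.method = "first")  # position of smallest id
  V <- matrix(0L, n, 6L)
  for (p in 1:6) {
    rows <- which(wmin == p)
    if (length(rows))
      V[rows, ] <- prism[rows, perms[p, ], drop = FALSE]
  }
  c1 <- pmin(V[, 2], V[, 6]) < pmin(V[, 3], V[, 5])
  tets <- matrix(0L, 3L * n, 4L)
  i1 <- which(c1); i2 <- which(!c1)
  if (length(i1)) {
    tets[i1, ] <- cbind(V[i1, 1], V[i1, 2], V[i1, 3], V[i1, 6])
    tets[n + i1, ] <- cbind(V[i1, 1], V[i1, 2], V[i1, 6], V[i1, 5])
    tets[2L * n + i1, ] <- cbind(V[i1, 1], V[i1, 5], V[i1, 6], V[i1, 4])
  }
  if (length(i2)) {
    tets[i2, ] <- cbind(V[i2, 1], V[i2, 2], V[i2, 3], V[i2, 5])
    tets[n + i2, ] <- cbind(V[i2, 1], V[i2, 5], V[i2, 3], V[i2, 6])
    tets[2L * n + i2, ] <- cbind(V[i2, 1], V[i2, 5], V[i2, 6], V[i2, 4])
  }
  ## group as (prism 1 tets, prism 2 tets, ...) for marker bookkeeping
  ord <- as.vector(t(matrix(seq_len(3L * n), n, 3L)))
  tets[ord, , drop = FALSE]
}

#' Generate a layered concentric-sphere tetrahedral mesh
#'
#' Structured generator: an icosphere surface triangulation is replicated
#' on a graded set of radial shells; shell gaps are filled with prisms
#' split into tets (diagonal choice by global vertex index, hence
#' conforming), and the innermost shell is connected to the center node by
#' a tet fan. All shell nodes lie exactly on their nominal radius; layer
#' interfaces and the exterior surface are tagged as facets.
#'
#' Facet markers: the exterior surface gets marker `max(layer_markers)+1`
#' (name `"exterior"`), the interface at `radii[k]` (k < K) gets marker
#' `max(layer_markers)+1+k` (name `"interface_k"`). The brain/CSF interface
#' of a four-layer head model is `"interface_1"`.
#'
#' @param spec a [sphere_layer_spec()].
#' @param seed integer; accepted for interface stability (the construction
#'   is deterministic and does not consume randomness).
#' @param max_level cap on the icosphere subdivision level (sizing guard).
#' @return a [tet_mesh()].
#' @export
generate_layered_sphere_mesh <- function(spec, seed = 1L, max_level = 7L) {
  stopifnot(inherits(spec, "sphere_layer_spec"))
  radii <- spec$radii
  K <- length(radii)
  el <- spec$edge_length

  ## angular subdivision level: chord of a level-L icosphere ~ 1.0515/2^L
  need <- ceiling(log2(1.0515 * radii / el))
  level <- max(0L, max(need))
  if (level > max_level)
    stop(sprintf(paste0("mesh sizing too fine: icosphere level %d needed ",
                        "(edge_length %.3g at radius %.3g); cap is %d"),
                 level, el[which.max(need)], radii[which.max(need)],
                 max_level))
  ico <- icosphere(level)
  nv <- nrow(ico$verts)

  ## radial shells: per layer, spacing <= edge_length of that layer;
  ## innermost shell at ~edge_length[1] (core is a fan from the origin)
  r0 <- min(el[1], radii[1] / 2)
  shells <- r0
  lower <- r0
  for (k in seq_len(K)) {
    nk <- max(1L, ceiling((radii[k] - lower) / el[k]))
    shells <- c(shells, lower + (radii[k] - lower) * seq_len(nk) / nk)
    lower <- radii[k]
  }
  S <- length(shells)
  if (S * nv > 5e6) stop("mesh sizing too fine: > 5e6 nodes requested")

  nodes <- matrix(0, 1L + S * nv, 3L)
  for (s in seq_len(S))
    nodes[1L + (s - 1L) * nv + seq_len(nv), ] <- ico$verts * shells[s]

  shell_ids <- function(s) 1L + (s - 1L) * nv + seq_len(nv)
  F0 <- ico$faces
  nf <- nrow(F0)

  ## core fan
  core <- cbind(1L, F0[, 1] + 1L, F0[, 2] + 1L, F0[, 3] + 1L)
  ## prisms per radial gap
  all_tets <- vector("list", S)
  all_tets[[1]] <- core
  for (s in seq_len(S - 1L)) {
    off_b <- 1L + (s - 1L) * nv
    off_t <- 1L + s * nv
    prisms <- cbind(F0 + off_b, F0 + off_t)
    all_tets[[s + 1L]] <- split_prisms(prisms)
  }
  tets <- do.call(rbind, all_tets)

  ## markers by radial band (gap midpoint radius)
  gap_mid <- c(shells[1] / 2, (shells[-S] + shells[-1]) / 2)
  gap_layer <- findInterval(gap_mid, c(0, radii), rightmost.closed = TRUE)
  gap_layer <- pmin(gap_layer, K)
  ncell_per <- c(nf, rep.int(3L * nf, S - 1L))
  cell_markers <- rep.int(spec$layer_markers[gap_layer], ncell_per)

  ## facets: exterior + internal layer interfaces
  base <- max(spec$layer_markers)
  ext_marker <- base + 1L
  facets <- F0 + (1L + (S - 1L) * nv)
  facet_markers <- rep.int(ext_marker, nf)
  marker_names <- setNames(c(spec$layer_markers, ext_marker),
                           c(paste0("layer_", seq_len(K)), "exterior"))
  if (K > 1L) {
    for (k in seq_len(K - 1L)) {
      s <- which.min(abs(shells - radii[k]))
      facets <- rbind(facets, F0 + (1L + (s - 1L) * nv))
      facet_markers <- c(facet_markers, rep.int(base + 1L + k, nf))
      marker_names <- c(marker_names,
                        setNames(base + 1L + k, paste0("interface_", k)))
    }
  }

  mesh <- tet_mesh(nodes, tets, cell_markers, facets, facet_markers,
                   marker_names, validate = FALSE)
  if (!is.null(spec$refine_region)) {
    rr <- spec$refine_region
    ctr <- rr$center
    pred <- function(x) sqrt(rowSums(sweep(x, 2, ctr)^2)) <= rr$radius
    mesh <- refine_mesh(mesh, pred, rr$min_inradius)
  }
  mesh
}

#' Generate a slab-in-bath tetrahedral mesh
#'
#' A rectangular tissue slab sitting on the bottom plane (z = 0) of a bath
#' of electrolyte, with optional electrode patches marked on the bottom
#' plane. Stand-in for a multi-electrode-array chamber: the bath is
#' modeled as a rectangular prism with footprint `bath_diameter` square
#' (cylindrical walls are not reproduced), meshed on a rectilinear grid
#' whose grid lines snap to slab and patch boundaries (so patch areas are
#' exact), each hex being split into 6 Kuhn tets.
#'
#' Markers: bath cells 1 (`"bath"`), slab cells 2 (`"slab"`); facets:
#' exterior 101, ground wall 102 (the x = +bath_diameter/2 wall, if
#' `ground`), patch k 110+k (`"patch_k"`).
#'
#' @param bath_diameter,bath_height bath footprint edge and height (m).
#' @param slab_dims length-3 vector (m): slab extents in x, y, z; the slab
#'   is centered in x/y and occupies `0 <= z <= slab_dims[3]`.
#' @param electrode_patches list of patches; each is a list with fields
#'   `shape` ("rect" or "disc"), `dims` (length-2 extents for rect, scalar
#'   radius for disc) and `center` (length-2 x/y position on z = 0).
#' @param max_cell target grid spacing (m); default `bath_diameter / 8`.
#' @param ground logical: mark the x = +bath_diameter/2 wall as a ground
#'   patch.
#' @return a [tet_mesh()].
#' @export
generate_slab_in_bath_mesh <- function(bath_diameter, bath_height,
                                       slab_dims,
                                       electrode_patches = list(),
                                       max_cell = bath_diameter / 8,
                                       ground = TRUE) {
  D <- bath_diameter; H <- bath_height
  sd3 <- as.numeric(slab_dims)
  if (length(sd3) != 3L) stop("slab_dims must have 3 entries")
  if (sd3[1] > D || sd3[2] > D || sd3[3] > H)
    stop("slab must fit inside the bath")

  patch_bbox <- function(p) {
    if (p$shape == "rect") {
      c(p$center[1] - p$dims[1] / 2, p$center[1] + p$dims[1] / 2,
        p$center[2] - p$dims[2] / 2, p$center[2] + p$dims[2] / 2)
    } else if (p$shape == "disc") {
      r <- p$dims[1]
      c(p$center[1] - r, p$center[1] + r, p$center[2] - r, p$center[2] + r)
    } else stop("unknown patch shape: ", p$shape)
  }
  np <- length(electrode_patches)
  if (np > 1L) {
    bb <- t(vapply(electrode_patches, patch_bbox, numeric(4)))
    for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
      if (bb[i, 1] < bb[j, 2] && bb[j, 1] < bb[i, 2] &&
          bb[i, 3] < bb[j, 4] && bb[j, 3] < bb[i, 4])
        stop(sprintf("electrode patches %d and %d overlap", i, j))
    }
  }

  snap_lines <- function(lo, hi, must, h) {
    must <- sort(unique(pmin(pmax(must, lo), hi)))
    pts <- unique(c(lo, must, hi))
    out <- numeric(0)
    for (i in seq_len(length(pts) - 1L)) {
      n <- max(1L, ceiling((pts[i + 1L] - pts[i]) / h))
      out <- c(out, pts[i] + (pts[i + 1L] - pts[i]) * (0:(n - 1L)) / n)
    }
    c(out, hi)
  }
  mustx <- c(-sd3[1] / 2, sd3[1] / 2)
  musty <- c(-sd3[2] / 2, sd3[2] / 2)
  for (p in electrode_patches) {
    b <- patch_bbox(p)
    mustx <- c(mustx, b[1:2]); musty <- c(musty, b[3:4])
  }
  xs <- snap_lines(-D / 2, D / 2, mustx, max_cell)
  ys <- snap_lines(-D / 2, D / 2, musty, max_cell)
  zs <- snap_lines(0, H, sd3[3], max_cell)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  if (nx * ny * nz > 2e6) stop("mesh sizing too fine: > 2e6 grid nodes")

  nid <- function(i, j, k) i + nx * ((j - 1L) + ny * (k - 1L))
  nodes <- cbind(rep(xs, times = ny * nz),
                 rep(rep(ys, each = nx), times = nz),
                 rep(zs, each = nx * ny))

  ## hex cells -> 6 Kuhn tets around the main diagonal v000-v111
  ci <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nz - 1L))
  cj <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nz - 1L)
  ck <- rep(seq_len(nz - 1L), each = (nx - 1L) * (ny - 1L))
  v000 <- nid(ci, cj, ck);         v100 <- nid(ci + 1L, cj, ck)
  v010 <- nid(ci, cj + 1L, ck);    v110 <- nid(ci + 1L, cj + 1L, ck)
  v001 <- nid(ci, cj, ck + 1L);    v101 <- nid(ci + 1L, cj, ck + 1L)
  v011 <- nid(ci, cj + 1L, ck + 1L); v111 <- nid(ci + 1L, cj + 1L, ck + 1L)
  tets <- rbind(cbind(v000, v100, v110, v111),
                cbind(v000, v110, v010, v111),
                cbind(v000, v010, v011, v111),
                cbind(v000, v011, v001, v111),
                cbind(v000, v001, v101, v111),
                cbind(v000, v101, v100, v111))
  storage.mode(tets) <- "integer"

  ## subdomains by centroid
  ctr <- (nodes[tets[, 1], , drop = FALSE] + nodes[tets[, 2], , drop = FALSE] +
          nodes[tets[, 3], , drop = FALSE] + nodes[tets[, 4], , drop = FALSE]) / 4
  in_slab <- abs(ctr[, 1]) < sd3[1] / 2 & abs(ctr[, 2]) < sd3[2] / 2 &
             ctr[, 3] < sd3[3]
  cell_markers <- ifelse(in_slab, 2L, 1L)

  mesh0 <- tet_mesh(nodes, tets, cell_markers, validate = FALSE)
  bf <- boundary_faces(mesh0)
  bc <- (nodes[bf[, 1], , drop = FALSE] + nodes[bf[, 2], , drop = FALSE] +
         nodes[bf[, 3], , drop = FALSE]) / 3
  fm <- rep.int(101L, nrow(bf))
  marker_names <- c(bath = 1L, slab = 2L, exterior = 101L)
  tolg <- 1e-9 * D
  if (ground) {
    on_wall <- abs(bc[, 1] - D / 2) < tolg
    fm[on_wall] <- 102L
    marker_names <- c(marker_names, ground = 102L)
  }
  in_patch <- function(p, xy) {
    if (p$shape == "rect")
      abs(xy[, 1] - p$center[1]) < p$dims[1] / 2 + tolg &
        abs(xy[, 2] - p$center[2]) < p$dims[2] / 2 + tolg
    else
      sqrt((xy[, 1] - p$center[1])^2 + (xy[, 2] - p$center[2])^2) <
        p$dims[1] + tolg
  }
  for (k in seq_len(np)) {
    on_bot <- abs(bc[, 3]) < tolg
    sel <- on_bot & in_patch(electrode_patches[[k]], bc[, 1:2, drop = FALSE])
    if (!any(sel)) stop(sprintf("electrode patch %d captured no facets", k))
    fm[sel] <- 110L + k
    marker_names <- c(marker_names, setNames(110L + k, paste0("patch_", k)))
  }
  tet_mesh(nodes, tets, cell_markers, bf, fm, marker_names,
           validate = FALSE)
}

#' Quasi-uniform sample points on a sphere
#'
#' Deterministic Fibonacci lattice of `n` points on the sphere of the given
#' radius, used as evaluation locations for surface potentials.
#'
#' @param radius sphere radius (m).
#' @param n number of points.
#' @return numeric `n` x 3 matrix of points with `|p| = radius`.
#' @export
surface_sample_points <- function(radius, n) {
  stopifnot(n >= 1, radius > 0)
  i <- seq_len(n) - 1L
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(s * cos(phi), s * sin(phi), z)
}
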