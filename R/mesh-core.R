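#' @importFrom stats fft sd setNames coef lm dist quantile
#' @importFrom utils head tail write.csv read.csv
NULL

#' Tetrahedral mesh with subdomain and facet markers
#'
#' The central geometry container of the package: a conforming tetrahedral
#' tessellation of a volume conductor domain, with an integer subdomain
#' marker per cell (tissue compartments) and integer markers on selected
#' boundary/interface triangles (exterior surface, electrode patches,
#' tissue interfaces).
#'
#' @param nodes numeric matrix, one row per node, columns x/y/z in meters.
#' @param tets integer matrix, one row per tetrahedron, 4 node indices
#'   (1-based). Reoriented on construction so every signed volume is
#'   positive.
#' @param cell_markers integer vector, one subdomain id per tet.
#' @param facets integer matrix (possibly 0 rows), one row per marked
#'   boundary/interface triangle, 3 node indices.
#' @param facet_markers integer vector, one id per marked facet.
#' @param marker_names optional named integer vector mapping labels to
#'   marker ids (both cell and facet ids may appear).
#' @param validate logical; run full invariant checks (duplicate nodes,
#'   facet incidence). Disable for very large programmatic meshes where the
#'   construction guarantees the invariants.
#'
#' @return An object of class `tet_mesh`: a list with fields `nodes`,
#'   `tets`, `cell_markers`, `facets`, `facet_markers`, `marker_names`.
#' @export
tet_mesh <- function(nodes, tets, cell_markers = NULL, facets = NULL,
                     facet_markers = NULL, marker_names = NULL,
                     validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3L) stop("nodes must have 3 columns (x, y, z)")
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(tets) != 4L) stop("tets must have 4 columns")
  if (is.null(cell_markers)) cell_markers <- rep(1L, nrow(tets))
  cell_markers <- as.integer(cell_markers)
  if (length(cell_markers) != nrow(tets))
    stop("cell_markers must have one entry per tet")
  if (is.null(facets)) facets <- matrix(integer(0), 0L, 3L)
  facets <- as.matrix(facets)
  storage.mode(facets) <- "integer"
  if (ncol(facets) != 3L && nrow(facets) > 0L)
    stop("facets must have 3 columns")
  if (is.null(facet_markers)) facet_markers <- integer(nrow(facets))
  facet_markers <- as.integer(facet_markers)
  if (length(facet_markers) != nrow(facets))
    stop("facet_markers must have one entry per facet")

  if (nrow(tets) > 0L) {
    rng <- range(tets)
    if (rng[1] < 1L || rng[2] > nrow(nodes))
      stop("tet node indices out of range")
    ## consistent orientation: positive signed volume
    v <- tet_signed_volumes(nodes, tets)
    flip <- which(v < 0)
    if (length(flip)) {
      tmp <- tets[flip, 3L]
      tets[flip, 3L] <- tets[flip, 4L]
      tets[flip, 4L] <- tmp
      v[flip] <- -v[flip]
    }
    if (any(v <= 0))
      stop("degenerate tetrahedra with zero volume present")
  }

  m <- structure(
    list(nodes = nodes, tets = tets, cell_markers = cell_markers,
         facets = facets, facet_markers = facet_markers,
         marker_names = marker_names),
    class = "tet_mesh")
  if (validate) validate_tet_mesh(m)
  m
}

#' Validate tet_mesh invariants
#'
#' Checks positive volumes, node index ranges, absence of duplicate nodes
#' (within 1e-12 m), that every marked facet is a face of at least one tet,
#' and mesh conformity (no face shared by more than two tets).
#'
#' @param mesh a `tet_mesh`.
#' @param tol duplicate-node tolerance in meters.
#' @return invisibly `TRUE`; stops with a message on violation.
#' @export
validate_tet_mesh <- function(mesh, tol = 1e-12) {
  nodes <- mesh$nodes; tets <- mesh$tets
  if (nrow(tets) > 0L) {
    v <- tet_signed_volumes(nodes, tets)
    if (any(v <= 0)) stop("non-positive tet volume")
  }
  ## duplicate nodes within tolerance: exact-duplicate detection on rounded
  ## coordinates (tol is far below any edge length used here)
  if (nrow(nodes) > 1L) {
    key <- paste(round(nodes[, 1] / tol), round(nodes[, 2] / tol),
                 round(nodes[, 3] / tol))
    if (anyDuplicated(key)) stop("duplicate nodes within tolerance")
  }
  ## conformity: a triangular face belongs to at most 2 tets
  if (nrow(tets) > 0L) {
    fk <- tet_face_keys(tets)
    cnt <- table(fk$key)
    if (any(cnt > 2L)) stop("non-conforming mesh: face shared by > 2 tets")
    ## every marked facet is a face of >= 1 tet
    if (nrow(mesh$facets) > 0L) {
      fkey <- face_key(mesh$facets)
      if (!all(fkey %in% fk$key))
        stop("marked facet is not a face of any tet")
    }
  }
  invisible(TRUE)
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("tet_mesh:", nrow(x$nodes), "nodes,", nrow(x$tets), "tets,",
      nrow(x$facets), "marked facets\n")
  cm <- sort(unique(x$cell_markers))
  cat("  cell markers:", paste(cm, collapse = " "), "\n")
  if (nrow(x$facets) > 0L)
    cat("  facet markers:", paste(sort(unique(x$facet_markers)),
                                  collapse = " "), "\n")
  if (!is.null(x$marker_names)) {
    nm <- x$marker_names
    cat("  names:", paste(names(nm), nm, sep = "=", collapse = " "), "\n")
  }
  v <- tet_volumes(x)
  cat(sprintf("  total volume %.6g m^3, bbox [%.4g, %.4g] x [%.4g, %.4g] x [%.4g, %.4g]\n",
              sum(v), min(x$nodes[, 1]), max(x$nodes[, 1]),
              min(x$nodes[, 2]), max(x$nodes[, 2]),
              min(x$nodes[, 3]), max(x$nodes[, 3])))
  invisible(x)
}

## signed volume = det[p2-p1, p3-p1, p4-p1] / 6, vectorized over tets
tet_signed_volumes <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  a <- nodes[tets[, 2], , drop = FALSE] - p1
  b <- nodes[tets[, 3], , drop = FALSE] - p1
  c <- nodes[tets[, 4], , drop = FALSE] - p1
  (a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
   a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
   a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Tetrahedron volumes
#' @param mesh a `tet_mesh`.
#' @return numeric vector of cell volumes in m^3.
#' @export
tet_volumes <- function(mesh) tet_signed_volumes(mesh$nodes, mesh$tets)

#' Cell centroids
#' @param mesh a `tet_mesh`.
#' @return numeric matrix, one row per tet.
#' @export
cell_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 2], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 3], , drop = FALSE] +
   mesh$nodes[mesh$tets[, 4], , drop = FALSE]) / 4
}

## triangle areas, vectorized; tris = integer matrix n x 3
triangle_areas <- function(nodes, tris) {
  a <- nodes[tris[, 2], , drop = FALSE] - nodes[tris[, 1], , drop = FALSE]
  b <- nodes[tris[, 3], , drop = FALSE] - nodes[tris[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Areas of marked facets
#' @param mesh a `tet_mesh`.
#' @param marker optional marker id; if given, only facets with this marker.
#' @return numeric vector of facet areas (m^2).
#' @export
facet_areas <- function(mesh, marker = NULL) {
  f <- mesh$facets
  if (!is.null(marker)) f <- f[mesh$facet_markers == marker, , drop = FALSE]
  if (nrow(f) == 0L) return(numeric(0))
  triangle_areas(mesh$nodes, f)
}

#' Tetrahedron inradii
#'
#' Inradius of a tet defined as 3 V / (sum of the four face areas).
#'
#' @param mesh a `tet_mesh`.
#' @return numeric vector of inradii in meters.
#' @export
tet_inradii <- function(mesh) {
  tets <- mesh$tets; nodes <- mesh$nodes
  v <- tet_signed_volumes(nodes, tets)
  fa <- triangle_areas(nodes, tets[, c(2, 3, 4), drop = FALSE]) +
        triangle_areas(nodes, tets[, c(1, 3, 4), drop = FALSE]) +
        triangle_areas(nodes, tets[, c(1, 2, 4), drop = FALSE]) +
        triangle_areas(nodes, tets[, c(1, 2, 3), drop = FALSE])
  3 * v / fa
}

## --- face bookkeeping helpers ---------------------------------------------

## string key of a triangle independent of vertex order
face_key <- function(tris) {
  s1 <- pmin(tris[, 1], tris[, 2], tris[, 3])
  s3 <- pmax(tris[, 1], tris[, 2], tris[, 3])
  s2 <- as.integer(tris[, 1]) + as.integer(tris[, 2]) +
        as.integer(tris[, 3]) - s1 - s3
  paste(s1, s2, s3, sep = "_")
}

## all 4 faces of every tet; returns list(faces = 4M x 3, cell = 4M, key)
tet_face_keys <- function(tets) {
  M <- nrow(tets)
  faces <- rbind(tets[, c(2, 3, 4), drop = FALSE],
                 tets[, c(1, 4, 3), drop = FALSE],
                 tets[, c(1, 2, 4), drop = FALSE],
                 tets[, c(1, 3, 2), drop = FALSE])
  list(faces = faces, cell = rep.int(seq_len(M), 4L), key = face_key(faces))
}

#' Boundary faces of a mesh
#'
#' Faces belonging to exactly one tet (the topological boundary of the
#' tessellated volume).
#'
#' @param mesh a `tet_mesh`.
#' @return integer matrix of boundary triangles (outward oriented as stored).
#' @export
boundary_faces <- function(mesh) {
  fk <- tet_face_keys(mesh$tets)
  cnt <- table(fk$key)
  single <- names(cnt)[cnt == 1L]
  fk$faces[fk$key %in% single, , drop = FALSE]
}

## edge keys (sorted pairs) for a 2-column matrix of node indices;
## numeric encoding is exact while nnodes < ~9e7 (kept well below by the
## generators' sizing guards)
edge_key <- function(e, nnodes) {
  pmin(e[, 1], e[, 2]) * (nnodes + 1) + pmax(e[, 1], e[, 2])
}

## the 6 edges of every tet (local pairs 12 13 14 23 24 34)
tet_edges <- function(tets) {
  rbind(tets[, c(1, 2), drop = FALSE], tets[, c(1, 3), drop = FALSE],
        tets[, c(1, 4), drop = FALSE], tets[, c(2, 3), drop = FALSE],
        tets[, c(2, 4), drop = FALSE], tets[, c(3, 4), drop = FALSE])
}

## unique edges of a mesh: list(edges = E x 2 sorted, index: for each of the
## 6M tet edges (column-block order 12,13,14,23,24,34), the row in `edges`)
unique_edges <- function(tets, nnodes = max(tets)) {
  te <- tet_edges(tets)
  te <- cbind(pmin(te[, 1], te[, 2]), pmax(te[, 1], te[, 2]))
  key <- edge_key(te, nnodes)
  u <- !duplicated(key)
  edges <- te[u, , drop = FALSE]
  idx <- match(key, key[u])
  list(edges = edges, index = idx)
}
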