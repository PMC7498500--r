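## Point location in a tet mesh via a uniform-grid spatial hash over cell
## bounding boxes, plus barycentric coordinates for P1/P2 interpolation
## and point-source assembly.

#' Build a point locator for a mesh
#'
#' Precomputes the inverse affine map of every cell and a uniform-grid
#' index of cell bounding boxes. Reused by [locate_points()],
#' [evaluate_field()] and point-source assembly.
#'
#' @param mesh a [tet_mesh()].
#' @param grid_n grid resolution per axis (default scales with cell count,
#'   capped at 80).
#' @return an opaque locator object.
#' @export
mesh_locator <- function(mesh, grid_n = NULL) {
  nodes <- mesh$nodes; tets <- mesh$tets
  M <- nrow(tets)
  p1 <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4], , drop = FALSE] - p1
  ## inverse of J = [e1 e2 e3] via cofactors; barycentric l2,l3,l4 = Jinv (x - p1)
  c11 <- e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]
  c12 <- e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3]
  c13 <- e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1]
  det <- e1[, 1] * c11 + e1[, 2] * c12 + e1[, 3] * c13
  ## rows of Jinv (scaled by det): row1 = e2 x e3, row2 = e3 x e1, row3 = e1 x e2
  r2 <- cbind(e3[, 2] * e1[, 3] - e3[, 3] * e1[, 2],
              e3[, 3] * e1[, 1] - e3[, 1] * e1[, 3],
              e3[, 1] * e1[, 2] - e3[, 2] * e1[, 1])
  r3 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  inv <- list(r1 = cbind(c11, c12, c13) / det, r2 = r2 / det, r3 = r3 / det,
              p1 = p1)

  lo <- apply(nodes, 2, min); hi <- apply(nodes, 2, max)
  span <- pmax(hi - lo, 1e-300)
  if (is.null(grid_n)) grid_n <- min(80L, max(4L, ceiling((M / 12)^(1 / 3))))
  ## cell bbox -> covered grid bins
  bmin <- pmin(pmin(nodes[tets[, 1], ], nodes[tets[, 2], ]),
               pmin(nodes[tets[, 3], ], nodes[tets[, 4], ]))
  bmax <- pmax(pmax(nodes[tets[, 1], ], nodes[tets[, 2], ]),
               pmax(nodes[tets[, 3], ], nodes[tets[, 4], ]))
  ix0 <- pmin(pmax(floor((bmin[, 1] - lo[1]) / span[1] * grid_n), 0), grid_n - 1)
  ix1 <- pmin(pmax(floor((bmax[, 1] - lo[1]) / span[1] * grid_n), 0), grid_n - 1)
  iy0 <- pmin(pmax(floor((bmin[, 2] - lo[2]) / span[2] * grid_n), 0), grid_n - 1)
  iy1 <- pmin(pmax(floor((bmax[, 2] - lo[2]) / span[2] * grid_n), 0), grid_n - 1)
  iz0 <- pmin(pmax(floor((bmin[, 3] - lo[3]) / span[3] * grid_n), 0), grid_n - 1)
  iz1 <- pmin(pmax(floor((bmax[, 3] - lo[3]) / span[3] * grid_n), 0), grid_n - 1)
  nrep <- as.integer((ix1 - ix0 + 1) * (iy1 - iy0 + 1) * (iz1 - iz0 + 1))
  cell_rep <- rep.int(seq_len(M), nrep)
  ## expand covered bins per cell (cells span few bins; loop over offsets)
  mx <- max(nrep)
  bins <- vector("list", 0L)
  binid <- numeric(sum(nrep)); pos <- 0L
  for (cx in 0:(max(ix1 - ix0))) for (cy in 0:(max(iy1 - iy0)))
    for (cz in 0:(max(iz1 - iz0))) {
      sel <- which(ix0 + cx <= ix1 & iy0 + cy <= iy1 & iz0 + cz <= iz1)
      if (!length(sel)) next
      ids <- (ix0[sel] + cx) + grid_n * ((iy0[sel] + cy) +
             grid_n * (iz0[sel] + cz))
      bins[[length(bins) + 1L]] <- cbind(ids, sel)
    }
  bm <- do.call(rbind, bins)
  ord <- order(bm[, 1])
  bm <- bm[ord, , drop = FALSE]
  ## bucket index: start positions per bin id
  structure(list(inv = inv, lo = lo, span = span, grid_n = grid_n,
                 bin_ids = bm[, 1], bin_cells = bm[, 2],
                 bin_starts = c(0L, cumsum(tabulate(bm[, 1] + 1L,
                                                    nbins = grid_n^3))),
                 mesh = mesh),
            class = "mesh_locator")
}

## barycentric coordinates of points in given cells (vectorized)
bary_coords <- function(loc, cells, pts) {
  inv <- loc$inv
  d <- pts - inv$p1[cells, , drop = FALSE]
  l2 <- rowSums(inv$r1[cells, , drop = FALSE] * d)
  l3 <- rowSums(inv$r2[cells, , drop = FALSE] * d)
  l4 <- rowSums(inv$r3[cells, , drop = FALSE] * d)
  cbind(1 - l2 - l3 - l4, l2, l3, l4)
}

#' Locate points in a mesh
#'
#' @param loc a [mesh_locator()] (or a `tet_mesh`, in which case a locator
#'   is built on the fly).
#' @param points numeric `n` x 3 matrix.
#' @param tol barycentric tolerance for containment.
#' @param nearest if `TRUE`, points not inside any cell are assigned to the
#'   cell with the least barycentric violation among candidates (flagged in
#'   the output); if `FALSE` such points raise an error.
#' @return list: `cell` (index, NA if not found), `bary` (`n` x 4),
#'   `inside` logical.
#' @export
locate_points <- function(loc, points, tol = 1e-10, nearest = FALSE) {
  if (inherits(loc, "tet_mesh")) loc <- mesh_locator(loc)
  pts <- matrix(as.numeric(points), ncol = 3L)
  n <- nrow(pts)
  g <- loc$grid_n
  ix <- pmin(pmax(floor((pts[, 1] - loc$lo[1]) / loc$span[1] * g), 0), g - 1)
  iy <- pmin(pmax(floor((pts[, 2] - loc$lo[2]) / loc$span[2] * g), 0), g - 1)
  iz <- pmin(pmax(floor((pts[, 3] - loc$lo[3]) / loc$span[3] * g), 0), g - 1)
  bin <- ix + g * (iy + g * iz)
  cell <- rep(NA_integer_, n)
  bary <- matrix(NA_real_, n, 4L)
  inside <- logical(n)
  for (i in seq_len(n)) {
    b <- bin[i]
    s0 <- loc$bin_starts[b + 1L]; s1 <- loc$bin_starts[b + 2L]
    if (s1 <= s0) next
    cand <- loc$bin_cells[(s0 + 1L):s1]
    bc <- bary_coords(loc, cand,
                      matrix(pts[i, ], length(cand), 3L, byrow = TRUE))
    viol <- -apply(bc, 1, min)
    j <- which.min(viol)
    if (viol[j] <= tol) {
      cell[i] <- cand[j]; bary[i, ] <- bc[j, ]; inside[i] <- TRUE
    } else if (nearest) {
      cell[i] <- cand[j]; bary[i, ] <- bc[j, ]
    }
  }
  if (!nearest && any(!inside)) {
    k <- which(!inside)[1]
    stop(sprintf("point (%g, %g, %g) is outside the mesh",
                 pts[k, 1], pts[k, 2], pts[k, 3]))
  }
  list(cell = cell, bary = bary, inside = inside)
}
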