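## Conforming red-green refinement. Marked cells are refined "red"
## (1 -> 8: four corner tets + the interior octahedron split along its
## shortest diagonal); neighbors are closed "green": a cell with exactly
## one refined edge is bisected, a cell whose three refined edges lie on
## one face gets a 1:4 face split, and any other hanging-edge pattern
## promotes the cell to red until the configuration is stable. Midpoints
## are plain edge midpoints (no boundary projection), so child volumes sum
## exactly to the parent volume and markers are inherited verbatim.

## local edge columns per face (faces opposite vertex 1..4);
## edge column order is 12, 13, 14, 23, 24, 34
.face_edge_cols <- list(c(4L, 5L, 6L),   # face (2,3,4), apex 1
                        c(2L, 3L, 6L),   # face (1,3,4), apex 2
                        c(1L, 3L, 5L),   # face (1,2,4), apex 3
                        c(1L, 2L, 4L))   # face (1,2,3), apex 4

#' Red-green refine a set of cells
#'
#' One conforming refinement pass: the given cells (plus any promoted
#' during green closure) are split 1:8; neighbor cells are split to remove
#' hanging nodes.
#'
#' @param mesh a [tet_mesh()].
#' @param cells integer vector of cell indices to refine.
#' @param snap_radii optional numeric vector of sphere radii (about the
#'   origin): a new midpoint whose parent edge endpoints both lie on one
#'   of these radii (within `1e-9` relative) is snapped back onto that
#'   sphere. Used for convergence studies on curved domains; note it
#'   trades the exact-volume-conservation property of pure subdivision
#'   for geometric fidelity.
#' @return the refined [tet_mesh()].
#' @export
refine_cells <- function(mesh, cells, snap_radii = NULL) {
  M <- nrow(mesh$tets)
  if (length(cells) == 0L) return(mesh)
  red <- logical(M)
  red[cells] <- TRUE
  tets <- mesh$tets
  nn <- nrow(mesh$nodes)
  ue <- unique_edges(tets, nn)
  eidx <- matrix(ue$index, M, 6L)  # per-cell unique-edge row ids

  ## green closure with promotion until stable; supported green patterns:
  ## 1 edge, 2 edges (any), 3 edges on one face
  refined_edge <- logical(nrow(ue$edges))
  repeat {
    refined_edge[] <- FALSE
    refined_edge[as.vector(eidx[red, , drop = FALSE])] <- TRUE
    hit <- matrix(refined_edge[eidx], M, 6L)
    cnt <- rowSums(hit)
    ok3 <- cnt == 3L & (
      (hit[, 4] & hit[, 5] & hit[, 6]) | (hit[, 2] & hit[, 3] & hit[, 6]) |
      (hit[, 1] & hit[, 3] & hit[, 5]) | (hit[, 1] & hit[, 2] & hit[, 4]))
    bad <- !red & cnt > 0L & cnt != 1L & cnt != 2L & !ok3
    if (!any(bad)) break
    red[bad] <- TRUE
  }

  ## midpoint nodes for refined edges
  ridx <- which(refined_edge)
  mid_of_edge <- integer(nrow(ue$edges))
  mid_of_edge[ridx] <- nn + seq_along(ridx)
  mids <- (mesh$nodes[ue$edges[ridx, 1], , drop = FALSE] +
           mesh$nodes[ue$edges[ridx, 2], , drop = FALSE]) / 2
  if (!is.null(snap_radii)) {
    ra <- sqrt(rowSums(mesh$nodes[ue$edges[ridx, 1], , drop = FALSE]^2))
    rb <- sqrt(rowSums(mesh$nodes[ue$edges[ridx, 2], , drop = FALSE]^2))
    for (R in snap_radii) {
      on_sph <- abs(ra - R) < 1e-9 * R & abs(rb - R) < 1e-9 * R
      if (any(on_sph)) {
        rm_ <- sqrt(rowSums(mids[on_sph, , drop = FALSE]^2))
        mids[on_sph, ] <- mids[on_sph, , drop = FALSE] * (R / rm_)
      }
    }
  }
  nodes <- rbind(mesh$nodes, mids)

  ## per-cell midpoint ids (0 where edge not refined)
  mid <- matrix(mid_of_edge[eidx], M, 6L)

  hit <- matrix(refined_edge[eidx], M, 6L)
  cnt <- rowSums(hit)

  out_tets <- list(); out_mark <- list()
  keep <- !red & cnt == 0L
  out_tets[[1]] <- tets[keep, , drop = FALSE]
  out_mark[[1]] <- mesh$cell_markers[keep]

  ## --- red cells -> 8 children ---
  ir <- which(red)
  if (length(ir)) {
    v <- tets[ir, , drop = FALSE]
    m12 <- mid[ir, 1]; m13 <- mid[ir, 2]; m14 <- mid[ir, 3]
    m23 <- mid[ir, 4]; m24 <- mid[ir, 5]; m34 <- mid[ir, 6]
    corners <- rbind(cbind(v[, 1], m12, m13, m14),
                     cbind(v[, 2], m12, m23, m24),
                     cbind(v[, 3], m13, m23, m34),
                     cbind(v[, 4], m14, m24, m34))
    ## octahedron: shortest of the 3 diagonals (deterministic tie-break)
    dl <- function(a, b) rowSums((nodes[a, , drop = FALSE] -
                                  nodes[b, , drop = FALSE])^2)
    d <- cbind(dl(m12, m34), dl(m13, m24), dl(m14, m23))
    choice <- max.col(-d, ties.method = "first")
    octa <- matrix(0L, 4L * length(ir), 4L)
    n_r <- length(ir)
    for (ch in 1:3) {
      rows <- which(choice == ch)
      if (!length(rows)) next
      if (ch == 1L) { a <- m12[rows]; b <- m34[rows]
        cyc <- cbind(m13[rows], m14[rows], m24[rows], m23[rows]) }
      else if (ch == 2L) { a <- m13[rows]; b <- m24[rows]
        cyc <- cbind(m12[rows], m14[rows], m34[rows], m23[rows]) }
      else { a <- m14[rows]; b <- m23[rows]
        cyc <- cbind(m12[rows], m24[rows], m34[rows], m13[rows]) }
      for (q in 1:4) {
        octa[(q - 1L) * n_r + rows, ] <-
          cbind(a, b, cyc[, q], cyc[, q %% 4L + 1L])
      }
    }
    out_tets[[2]] <- rbind(corners, octa)
    out_mark[[2]] <- rep.int(mesh$cell_markers[ir], 8L)
  }

  epairs <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                  c(2L, 3L), c(2L, 4L), c(3L, 4L))

  ## --- green: 1 refined edge -> bisection ---
  ig <- which(!red & cnt == 1L)
  if (length(ig)) {
    ecol <- max.col(hit[ig, , drop = FALSE], ties.method = "first")
    v <- tets[ig, , drop = FALSE]
    mm <- mid[cbind(ig, ecol)]
    i1 <- epairs[ecol, 1]; i2 <- epairs[ecol, 2]
    t1 <- v; t1[cbind(seq_along(ig), i1)] <- mm
    t2 <- v; t2[cbind(seq_along(ig), i2)] <- mm
    out_tets[[3]] <- rbind(t1, t2)
    out_mark[[3]] <- rep.int(mesh$cell_markers[ig], 2L)
  }

  ## --- green: 2 refined edges ---
  i2e <- which(!red & cnt == 2L)
  if (length(i2e)) {
    h2 <- hit[i2e, , drop = FALSE]
    c1 <- max.col(h2, ties.method = "first")
    c2 <- max.col(h2, ties.method = "last")
    opp <- (c1 == 1L & c2 == 6L) | (c1 == 2L & c2 == 5L) |
           (c1 == 3L & c2 == 4L)
    v <- tets[i2e, , drop = FALSE]
    m1 <- mid[cbind(i2e, c1)]; m2 <- mid[cbind(i2e, c2)]
    kid_list <- list()
    ## (b) opposite edges (no shared vertex): 1 -> 4
    io <- which(opp)
    if (length(io)) {
      a <- v[cbind(io, epairs[c1[io], 1])]
      b <- v[cbind(io, epairs[c1[io], 2])]
      cc <- v[cbind(io, epairs[c2[io], 1])]
      dd <- v[cbind(io, epairs[c2[io], 2])]
      ma <- m1[io]; mb <- m2[io]
      kid_list$opp <- rbind(cbind(a, ma, cc, mb), cbind(a, ma, mb, dd),
                            cbind(ma, b, cc, mb), cbind(ma, b, mb, dd))
      kid_list$opp_m <- rep.int(mesh$cell_markers[i2e[io]], 4L)
    }
    ## (a) edges sharing a vertex p on face (p,q,r): 1 -> 3, quad diagonal
    ## through the smaller of q, r (matches the neighbor's choice)
    is_ <- which(!opp)
    if (length(is_)) {
      e1a <- epairs[c1[is_], 1]; e1b <- epairs[c1[is_], 2]
      e2a <- epairs[c2[is_], 1]; e2b <- epairs[c2[is_], 2]
      ## local index of shared vertex p, and q (other end of edge 1),
      ## r (other end of edge 2)
      pl <- ifelse(e1a == e2a | e1a == e2b, e1a, e1b)
      ql <- ifelse(pl == e1a, e1b, e1a)
      rl <- ifelse(pl == e2a, e2b, e2a)
      sl <- 10L - pl - ql - rl  # the apex (local ids sum to 10)
      rows <- seq_along(is_)
      p <- v[cbind(is_, pl)]; q <- v[cbind(is_, ql)]
      r <- v[cbind(is_, rl)]; s <- v[cbind(is_, sl)]
      mpq <- m1[is_]; mpr <- m2[is_]
      t1 <- cbind(s, p, mpq, mpr)
      qlt <- q < r
      t2 <- matrix(0L, length(is_), 4L); t3 <- t2
      t2[qlt, ] <- cbind(s[qlt], mpq[qlt], q[qlt], mpr[qlt])
      t3[qlt, ] <- cbind(s[qlt], q[qlt], r[qlt], mpr[qlt])
      t2[!qlt, ] <- cbind(s[!qlt], mpq[!qlt], q[!qlt], r[!qlt])
      t3[!qlt, ] <- cbind(s[!qlt], mpq[!qlt], r[!qlt], mpr[!qlt])
      kid_list$sha <- rbind(t1, t2, t3)
      kid_list$sha_m <- rep.int(mesh$cell_markers[i2e[is_]], 3L)
    }
    out_tets[[5]] <- rbind(kid_list$opp, kid_list$sha)
    out_mark[[5]] <- c(kid_list$opp_m, kid_list$sha_m)
  }

  ## --- green: 3 refined edges on one face -> 1:4 face split ---
  i3 <- which(!red & cnt == 3L)
  if (length(i3)) {
    h3 <- hit[i3, , drop = FALSE]
    face <- integer(length(i3))
    for (fc in 1:4) {
      cols <- .face_edge_cols[[fc]]
      sel <- h3[, cols[1]] & h3[, cols[2]] & h3[, cols[3]]
      face[sel] <- fc
    }
    stopifnot(all(face > 0L))
    v <- tets[i3, , drop = FALSE]
    fverts <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L),
                    c(1L, 2L, 3L))
    ## local edge col for pair (i,j)
    paircol <- matrix(0L, 4, 4)
    paircol[1, 2] <- paircol[2, 1] <- 1L; paircol[1, 3] <- paircol[3, 1] <- 2L
    paircol[1, 4] <- paircol[4, 1] <- 3L; paircol[2, 3] <- paircol[3, 2] <- 4L
    paircol[2, 4] <- paircol[4, 2] <- 5L; paircol[3, 4] <- paircol[4, 3] <- 6L
    n3 <- length(i3)
    kids <- matrix(0L, 4L * n3, 4L)
    for (fc in 1:4) {
      rows <- which(face == fc)
      if (!length(rows)) next
      p <- fverts[fc, 1]; q <- fverts[fc, 2]; r <- fverts[fc, 3]
      apex <- v[rows, fc]
      vp <- v[rows, p]; vq <- v[rows, q]; vr <- v[rows, r]
      mpq <- mid[i3[rows], paircol[p, q]]
      mqr <- mid[i3[rows], paircol[q, r]]
      mrp <- mid[i3[rows], paircol[r, p]]
      kids[rows, ] <- cbind(apex, vp, mpq, mrp)
      kids[n3 + rows, ] <- cbind(apex, vq, mqr, mpq)
      kids[2L * n3 + rows, ] <- cbind(apex, vr, mrp, mqr)
      kids[3L * n3 + rows, ] <- cbind(apex, mpq, mqr, mrp)
    }
    out_tets[[4]] <- kids
    out_mark[[4]] <- rep.int(mesh$cell_markers[i3], 4L)
  }

  new_tets <- do.call(rbind, out_tets)
  new_mark <- unlist(out_mark)

  ## --- marked facets: split to match (0, 1 or 3 refined edges) ---
  facets <- mesh$facets; fmark <- mesh$facet_markers
  if (nrow(facets) > 0L) {
    fe <- rbind(facets[, c(1, 2)], facets[, c(2, 3)], facets[, c(3, 1)])
    fkey <- edge_key(fe, nn)
    ekey <- edge_key(ue$edges, nn)
    feidx <- match(fkey, ekey)
    fref <- matrix(refined_edge[feidx], nrow(facets), 3L)  # edges 12,23,31
    fmid <- matrix(mid_of_edge[feidx], nrow(facets), 3L)
    fcnt <- rowSums(fref)
    newf <- list(); newm <- list()
    k0 <- fcnt == 0L
    newf[[1]] <- facets[k0, , drop = FALSE]; newm[[1]] <- fmark[k0]
    k1 <- which(fcnt == 1L)
    if (length(k1)) {
      ec <- max.col(fref[k1, , drop = FALSE], ties.method = "first")
      ## edge ec connects verts (ec, ec%%3+1); remaining vert other
      a <- facets[cbind(k1, ec)]
      b <- facets[cbind(k1, ec %% 3L + 1L)]
      c_ <- facets[cbind(k1, (ec + 1L) %% 3L + 1L)]
      m <- fmid[cbind(k1, ec)]
      newf[[2]] <- rbind(cbind(c_, a, m), cbind(c_, m, b))
      newm[[2]] <- rep.int(fmark[k1], 2L)
    }
    k2 <- which(fcnt == 2L)
    if (length(k2)) {
      fr <- fref[k2, , drop = FALSE]
      ## shared vertex: edges (12,23) -> vert 2; (23,31) -> 3; (12,31) -> 1
      pl <- ifelse(fr[, 1] & fr[, 2], 2L, ifelse(fr[, 2] & fr[, 3], 3L, 1L))
      ql <- pl %% 3L + 1L          # next vertex (edge p-q is refined)
      rl <- (pl + 1L) %% 3L + 1L   # previous vertex (edge p-r is refined)
      ## edge column joining verts (i, i%%3+1) is column i
      col_of <- function(i, j) ifelse(i %% 3L + 1L == j, i, j)
      cpq <- col_of(pl, ql); cpr <- col_of(rl, pl)
      p <- facets[cbind(k2, pl)]; q <- facets[cbind(k2, ql)]
      r <- facets[cbind(k2, rl)]
      mpq <- fmid[cbind(k2, cpq)]; mpr <- fmid[cbind(k2, cpr)]
      qlt <- q < r
      f1 <- cbind(p, mpq, mpr)
      f2 <- matrix(0L, length(k2), 3L); f3 <- f2
      f2[qlt, ] <- cbind(mpq[qlt], q[qlt], mpr[qlt])
      f3[qlt, ] <- cbind(q[qlt], r[qlt], mpr[qlt])
      f2[!qlt, ] <- cbind(mpq[!qlt], q[!qlt], r[!qlt])
      f3[!qlt, ] <- cbind(mpq[!qlt], r[!qlt], mpr[!qlt])
      newf[[4]] <- rbind(f1, f2, f3)
      newm[[4]] <- rep.int(fmark[k2], 3L)
    }
    k3 <- which(fcnt == 3L)
    if (length(k3)) {
      p <- facets[k3, 1]; q <- facets[k3, 2]; r <- facets[k3, 3]
      mpq <- fmid[k3, 1]; mqr <- fmid[k3, 2]; mrp <- fmid[k3, 3]
      newf[[3]] <- rbind(cbind(p, mpq, mrp), cbind(q, mqr, mpq),
                         cbind(r, mrp, mqr), cbind(mpq, mqr, mrp))
      newm[[3]] <- rep.int(fmark[k3], 4L)
    }
    facets <- do.call(rbind, newf)
    fmark <- unlist(newm)
  }

  tet_mesh(nodes, new_tets, new_mark, facets, fmark, mesh$marker_names,
           validate = FALSE)
}

#' Refine a mesh in a region until an inradius bound is met
#'
#' Repeatedly applies red-green refinement to every cell whose centroid
#' lies in the region and whose inradius exceeds `min_inradius`, until no
#' such cell remains. Markers are inherited by children and the mesh stays
#' conforming.
#'
#' @param mesh a [tet_mesh()].
#' @param region predicate: function taking an `n x 3` matrix of cell
#'   centroids, returning a logical vector.
#' @param min_inradius refine cells in the region while their inradius
#'   (3V / surface area) exceeds this bound (m).
#' @param max_passes safety cap on refinement sweeps.
#' @param snap_radii passed to [refine_cells()]: sphere radii onto which
#'   boundary/interface midpoints are projected.
#' @return the refined [tet_mesh()].
#' @export
refine_mesh <- function(mesh, region, min_inradius, max_passes = 12L,
                        snap_radii = NULL) {
  stopifnot(min_inradius > 0)
  for (pass in seq_len(max_passes)) {
    ctr <- cell_centroids(mesh)
    marked <- which(region(ctr) & tet_inradii(mesh) > min_inradius)
    if (!length(marked)) return(mesh)
    mesh <- refine_cells(mesh, marked, snap_radii = snap_radii)
  }
  ctr <- cell_centroids(mesh)
  if (any(region(ctr) & tet_inradii(mesh) > min_inradius))
    stop("refinement did not reach the requested inradius within max_passes")
  mesh
}
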