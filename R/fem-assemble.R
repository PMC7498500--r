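## Lagrangian FEM assembly on tet meshes. P1 uses closed-form element
## matrices; P2 uses exact-degree quadrature. The complex admittivity
## operator is assembled in the real block formulation: unknowns
## [u_r; u_i] with operator [[A(y_r), -A(y_i)], [A(y_i), A(y_r)]], which
## is the matrix form of -div(y grad u) = f split into coupled real PDEs.

## 4-point tet rule, degree 2 (exact for grad P2 . grad P2)
.tet_quad <- function() {
  a <- 0.5854101966249685; b <- 0.1381966011250105
  list(l = rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a)),
       w = rep(0.25, 4))
}

## 6-point triangle rule, degree 4 (exact for P2 . P2)
.tri_quad <- function() {
  a1 <- 0.445948490915965; a2 <- 0.108103018168070
  b1 <- 0.091576213509771; b2 <- 0.816847572980459
  w1 <- 0.223381589678011; w2 <- 0.109951743655322
  list(l = rbind(c(a1, a1, a2), c(a1, a2, a1), c(a2, a1, a1),
                 c(b1, b1, b2), c(b1, b2, b1), c(b2, b1, b1)),
       w = c(w1, w1, w1, w2, w2, w2))
}

## local edge vertex pairs of a tet (order 12, 13, 14, 23, 24, 34)
.tet_epairs <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                     c(2L, 3L), c(2L, 4L), c(3L, 4L))

## P2 basis values at barycentric coords l (vector of 4): 10 values,
## order (v1..v4, e12, e13, e14, e23, e24, e34)
.p2_basis <- function(l) {
  c(l * (2 * l - 1),
    4 * l[.tet_epairs[, 1]] * l[.tet_epairs[, 2]])
}

.p1_basis <- function(l) l

## per-cell gradients of barycentric coords: list of four M x 3 matrices
.bary_grads <- function(nodes, tets) {
  p1 <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - p1
  e2 <- nodes[tets[, 3], , drop = FALSE] - p1
  e3 <- nodes[tets[, 4], , drop = FALSE] - p1
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c23 <- cr(e2, e3); c31 <- cr(e3, e1); c12 <- cr(e1, e2)
  det <- rowSums(e1 * c23)
  g2 <- c23 / det; g3 <- c31 / det; g4 <- c12 / det
  list(g1 = -(g2 + g3 + g4), g2 = g2, g3 = g3, g4 = g4, vol = det / 6)
}

## numeric or complex per-cell material values from a marker map.
## map entries: scalar, 3x3 matrix, or `admittivity` objects.
.material_values <- function(mesh, material_map, part = c("complex", "real")) {
  part <- match.arg(part)
  mk <- unique(mesh$cell_markers)
  miss <- setdiff(as.character(mk), names(material_map))
  if (length(miss))
    stop("material_map is missing marker(s): ", paste(miss, collapse = ", "))
  get1 <- function(v) if (inherits(v, "admittivity")) v$value else v
  vals <- lapply(material_map, get1)
  is_tensor <- vapply(vals, is.matrix, logical(1))
  if (any(is_tensor) != all(is_tensor))
    stop("material_map mixes scalar and tensor entries")
  tensor <- any(is_tensor)
  idx <- match(as.character(mesh$cell_markers), names(material_map))
  if (tensor) {
    arr <- vapply(vals, function(m) as.vector(m), numeric(9) + 0i)
    out <- t(arr)[idx, , drop = FALSE]   # M x 9, column-major tensor
  } else {
    out <- unlist(vals, use.names = FALSE)[idx]
  }
  if (part == "real") out <- Re(out) + 0 else out <- out + 0i
  list(values = out, tensor = tensor)
}

## core stiffness triplets for one material part (complex values allowed);
## returns sparse pattern contributions for the scalar Laplace-type form
## int y grad u . grad v dx
.stiffness_triplets <- function(mesh, mat, order, dofinfo) {
  bg <- .bary_grads(mesh$nodes, mesh$tets)
  vol <- bg$vol
  M <- nrow(mesh$tets)
  yv <- mat$values
  ## gi sig gj for possibly tensor material
  dotsig <- function(gi, gj) {
    if (!mat$tensor) {
      yv * rowSums(gi * gj)
    } else {
      ## sum_ab gi_a sig_ab gj_b, tensor stored column-major in yv cols
      acc <- 0
      for (a in 1:3) for (b in 1:3)
        acc <- acc + gi[, a] * yv[, a + 3 * (b - 1)] * gj[, b]
      acc
    }
  }
  if (order == 1L) {
    G <- list(bg$g1, bg$g2, bg$g3, bg$g4)
    nl <- 4L
    conn <- mesh$tets
    ii <- jj <- integer(16L * M)
    xx <- if (is.complex(yv)) complex(16L * M) else numeric(16L * M)
    k <- 0L
    for (i in 1:4) for (j in 1:4) {
      xx[k + seq_len(M)] <- vol * dotsig(G[[i]], G[[j]])
      ii[k + seq_len(M)] <- conn[, i]
      jj[k + seq_len(M)] <- conn[, j]
      k <- k + M
    }
    list(i = ii, j = jj, x = xx)
  } else {
    ## P2: quadrature; local gradients of the 10 basis functions depend on
    ## the quadrature point through the barycentric values only
    q <- .tet_quad()
    conn <- cbind(mesh$tets, dofinfo$nn + dofinfo$cell_edges)
    Gl <- list(bg$g1, bg$g2, bg$g3, bg$g4)
    nl <- 10L
    nq <- length(q$w)
    ## accumulate element matrices
    Ke <- vector("list", nl * nl)
    for (qi in seq_len(nq)) {
      l <- q$l[qi, ]
      ## gradients at this point: vertices (4 l_i - 1) grad l_i;
      ## edges 4 (l_a grad l_b + l_b grad l_a)
      Gq <- vector("list", nl)
      for (i in 1:4) Gq[[i]] <- (4 * l[i] - 1) * Gl[[i]]
      for (e in 1:6) {
        a <- .tet_epairs[e, 1]; b <- .tet_epairs[e, 2]
        Gq[[4L + e]] <- 4 * (l[a] * Gl[[b]] + l[b] * Gl[[a]])
      }
      for (i in seq_len(nl)) for (j in seq_len(nl)) {
        contrib <- q$w[qi] * vol * dotsig(Gq[[i]], Gq[[j]])
        k <- (i - 1L) * nl + j
        Ke[[k]] <- if (is.null(Ke[[k]])) contrib else Ke[[k]] + contrib
      }
    }
    ii <- jj <- integer(nl * nl * M)
    xx <- if (is.complex(yv)) complex(nl * nl * M) else numeric(nl * nl * M)
    k <- 0L
    for (i in seq_len(nl)) for (j in seq_len(nl)) {
      xx[k + seq_len(M)] <- Ke[[(i - 1L) * nl + j]]
      ii[k + seq_len(M)] <- conn[, i]
      jj[k + seq_len(M)] <- conn[, j]
      k <- k + M
    }
    list(i = ii, j = jj, x = xx)
  }
}

.dof_info <- function(mesh, order) {
  nn <- nrow(mesh$nodes)
  if (order == 1L)
    return(list(order = 1L, nn = nn, ndof = nn, cell_edges = NULL,
                ue = NULL))
  ue <- unique_edges(mesh$tets, nn)
  list(order = 2L, nn = nn, ndof = nn + nrow(ue$edges),
       cell_edges = matrix(ue$index, nrow(mesh$tets), 6L), ue = ue)
}

## integral of each basis function over the volume (zero-mean weights)
.volume_weights <- function(mesh, dofinfo) {
  v <- tet_volumes(mesh)
  w <- numeric(dofinfo$ndof)
  if (dofinfo$order == 1L) {
    for (i in 1:4)
      w <- w + unname(tapply2(mesh$tets[, i], v / 4, dofinfo$ndof))
  } else {
    for (i in 1:4)
      w <- w + tapply2(mesh$tets[, i], -v / 20, dofinfo$ndof)
    for (e in 1:6)
      w <- w + tapply2(dofinfo$nn + dofinfo$cell_edges[, e], v / 5,
                       dofinfo$ndof)
  }
  w
}

## fast "sum x by integer index" into a vector of length n
tapply2 <- function(idx, x, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Assemble the real (resistive) stiffness system
#'
#' Builds the sparse operator `A_ij = int_Omega sigma grad phi_i . grad
#' phi_j dx` over all subdomains, with homogeneous Neumann boundary
#' conditions (the natural BC of the weak form). Pure-Neumann systems have
#' the constants as nullspace; a zero-mean reference is applied at solve
#' time unless Robin electrodes are added.
#'
#' @param mesh a [tet_mesh()].
#' @param material_map named list: cell marker (as character) to
#'   conductivity, either a positive scalar (S/m), a symmetric positive
#'   definite 3x3 tensor, or an `admittivity` (its real part is used).
#' @param order element order, 1 (linear) or 2 (quadratic).
#' @return object of class `fem_system`, mode `"real"`.
#' @export
assemble_stiffness <- function(mesh, material_map, order = 1L) {
  order <- as.integer(order)
  stopifnot(order %in% c(1L, 2L))
  v <- tet_volumes(mesh)
  if (any(v <= 0)) stop("zero-volume cell in mesh")
  dofinfo <- .dof_info(mesh, order)
  mat <- .material_values(mesh, material_map, "real")
  tr <- .stiffness_triplets(mesh, mat, order, dofinfo)
  A <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(dofinfo$ndof, dofinfo$ndof))
  structure(list(mode = "real", mesh = mesh, dofinfo = dofinfo,
                 A_r = A, A_i = NULL,
                 b_r = numeric(dofinfo$ndof), b_i = NULL,
                 electrodes = list(), has_robin = FALSE,
                 vol_weights = .volume_weights(mesh, dofinfo)),
            class = "fem_system")
}

#' Assemble the complex-admittivity operator in real block form
#'
#' For admittivity `y = y_r + j y_i` the operator acting on `[u_r; u_i]`
#' is `[[A(y_r), -A(y_i)], [A(y_i), A(y_r)]]`; with `y_i = 0` it reduces
#' to two decoupled copies of the real system.
#'
#' @param mesh a [tet_mesh()].
#' @param material_map named list: cell marker to complex admittivity
#'   (complex scalar, complex 3x3 tensor, or [admittivity_of()] objects).
#' @param order element order 1 or 2.
#' @return object of class `fem_system`, mode `"complex_block"`.
#' @export
assemble_complex_block <- function(mesh, material_map, order = 1L) {
  order <- as.integer(order)
  stopifnot(order %in% c(1L, 2L))
  dofinfo <- .dof_info(mesh, order)
  mat <- .material_values(mesh, material_map, "complex")
  tr <- .stiffness_triplets(mesh, mat, order, dofinfo)
  n <- dofinfo$ndof
  A_r <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = Re(tr$x),
                              dims = c(n, n))
  A_i <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = Im(tr$x),
                              dims = c(n, n))
  structure(list(mode = "complex_block", mesh = mesh, dofinfo = dofinfo,
                 A_r = A_r, A_i = A_i,
                 b_r = numeric(n), b_i = numeric(n),
                 electrodes = list(), has_robin = FALSE,
                 vol_weights = .volume_weights(mesh, dofinfo)),
            class = "fem_system")
}

## facet mass matrix triplets and basis surface integrals for the facets
## with a given marker. Returns list(i, j, x) over scalar dofs and m =
## sparse named vector of int N_i ds, S = total area.
.facet_surface_ops <- function(system, marker) {
  mesh <- system$mesh
  sel <- mesh$facet_markers == marker
  if (!any(sel)) stop("no facets carry marker ", marker)
  tris <- mesh$facets[sel, , drop = FALSE]
  areas <- triangle_areas(mesh$nodes, tris)
  S <- sum(areas)
  if (S <= 0) stop("electrode marker ", marker, " has zero area")
  n <- system$dofinfo$ndof
  if (system$dofinfo$order == 1L) {
    ## P1 triangle mass: A/12 * (2 on diag, 1 off)
    ii <- jj <- integer(9L * nrow(tris)); xx <- numeric(9L * nrow(tris))
    k <- 0L
    for (i in 1:3) for (j in 1:3) {
      xx[k + seq_len(nrow(tris))] <- areas / 12 * (1 + (i == j))
      ii[k + seq_len(nrow(tris))] <- tris[, i]
      jj[k + seq_len(nrow(tris))] <- tris[, j]
      k <- k + nrow(tris)
    }
    m <- tapply2(as.vector(tris), rep(areas / 3, 3L), n)
  } else {
    ## P2 triangle: 6 local dofs = 3 verts + 3 edge dofs (12, 23, 31)
    ue <- system$dofinfo$ue
    nn <- system$dofinfo$nn
    fe <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
    eidx <- match(edge_key(fe, nn),
                  edge_key(ue$edges, nn))
    conn <- cbind(tris, nn + matrix(eidx, nrow(tris), 3L))
    q <- .tri_quad()
    basis <- function(l) c(l * (2 * l - 1),
                           4 * l[c(1, 2, 3)] * l[c(2, 3, 1)])
    Me <- matrix(0, 6, 6)
    for (qi in seq_along(q$w)) {
      bb <- basis(q$l[qi, ])
      Me <- Me + q$w[qi] * tcrossprod(bb)
    }
    me <- rowSums(vapply(seq_along(q$w),
                         function(qi) q$w[qi] * basis(q$l[qi, ]),
                         numeric(6)))
    nt <- nrow(tris)
    ii <- jj <- integer(36L * nt); xx <- numeric(36L * nt)
    k <- 0L
    for (i in 1:6) for (j in 1:6) {
      xx[k + seq_len(nt)] <- areas * Me[i, j]
      ii[k + seq_len(nt)] <- conn[, i]
      jj[k + seq_len(nt)] <- conn[, j]
      k <- k + nt
    }
    m <- numeric(n)
    for (i in 1:6) m <- m + tapply2(conn[, i], areas * me[i], n)
  }
  list(i = ii, j = jj, x = xx, m = m, S = S)
}

#' Electrode specification
#'
#' @param facet_marker facet marker id of the electrode patch.
#' @param role `"stimulating"` (known metal potential), `"ground"`
#'   (metal potential 0) or `"recording"` (floating: metal potential is an
#'   unknown).
#' @param interface an [interface_model()], or a fixed complex surface
#'   admittance in S/m^2.
#' @param phi_metal metal potential (V); required for stimulating, forced
#'   to 0 for ground, must be absent for recording electrodes.
#' @return object of class `electrode_spec`.
#' @export
electrode_spec <- function(facet_marker,
                           role = c("stimulating", "recording", "ground"),
                           interface, phi_metal = NULL) {
  role <- match.arg(role)
  if (role == "stimulating" && is.null(phi_metal))
    stop("stimulating electrode needs phi_metal")
  if (role == "ground") phi_metal <- 0
  if (role == "recording" && !is.null(phi_metal))
    stop("recording electrodes have no prescribed phi_metal")
  structure(list(facet_marker = as.integer(facet_marker), role = role,
                 interface = interface, phi_metal = phi_metal),
            class = "electrode_spec")
}

## resolve electrode interface admittance at f
.electrode_y <- function(electrode, f) {
  if (inherits(electrode$interface, "interface_model"))
    surface_admittance(electrode$interface, f)
  else as.complex(electrode$interface)
}

#' Add a Robin electrode-interface boundary condition
#'
#' Adds the weak-form interface terms `int_Gamma y (u - phi_metal) v ds`
#' for the electrode's facet patch: the facet mass matrix scaled by the
#' surface admittance `y = g + j b` goes into the operator (in block mode
#' the `[[g, -b], [b, g]]` pattern) and the `phi_metal` terms into the
#' right-hand side. Recording electrodes get their operator term here, but
#' their unknown metal potential must then be added with
#' [add_floating_electrode()] (solving without it is an error).
#'
#' @param system a `fem_system`.
#' @param electrode an [electrode_spec()].
#' @param f frequency (Hz) at which the interface admittance is evaluated.
#' @return the updated `fem_system`.
#' @export
add_robin_interface <- function(system, electrode, f) {
  stopifnot(inherits(system, "fem_system"),
            inherits(electrode, "electrode_spec"))
  y <- .electrode_y(electrode, f)
  g <- Re(y); b <- Im(y)
  if (system$mode == "real" && abs(b) > 0)
    stop("reactive interface admittance requires a complex_block system")
  ops <- .facet_surface_ops(system, electrode$facet_marker)
  n <- system$dofinfo$ndof
  Ms <- Matrix::sparseMatrix(i = ops$i, j = ops$j, x = ops$x,
                             dims = c(n, n))
  system$A_r <- system$A_r + g * Ms
  if (system$mode == "complex_block") system$A_i <- system$A_i + b * Ms
  entry <- list(marker = electrode$facet_marker, role = electrode$role,
                y = y, m = ops$m, S = ops$S,
                phi_metal = electrode$phi_metal, float_index = NA_integer_)
  if (electrode$role %in% c("stimulating", "ground")) {
    pm <- electrode$phi_metal
    system$b_r <- system$b_r + (g * Re(pm) - b * Im(pm)) * ops$m
    if (system$mode == "complex_block")
      system$b_i <- system$b_i + (g * Im(pm) + b * Re(pm)) * ops$m
  }
  system$electrodes <- c(system$electrodes, list(entry))
  system$has_robin <- TRUE
  system
}

#' Add a floating (recording) electrode unknown
#'
#' Introduces the scalar unknown metal potential of a recording electrode
#' (two scalars, real and imaginary, in block mode), coupled through the
#' Robin terms, plus the Lagrange constraint `phi_metal = (1/S) int_S phi
#' dS` defining the metal potential as the surface average of the tissue
#' potential. Call after [add_robin_interface()] for the same electrode.
#'
#' @param system a `fem_system`.
#' @param electrode the recording [electrode_spec()].
#' @param f frequency (Hz), must match the Robin call.
#' @return the updated `fem_system`.
#' @export
add_floating_electrode <- function(system, electrode, f) {
  stopifnot(electrode$role == "recording")
  idx <- which(vapply(system$electrodes, function(e)
    e$marker == electrode$facet_marker & e$role == "recording" &
      is.na(e$float_index), logical(1)))
  if (!length(idx))
    stop("add_robin_interface must be called first for recording marker ",
         electrode$facet_marker)
  nfl <- sum(!is.na(vapply(system$electrodes,
                           function(e) e$float_index, NA_integer_)))
  system$electrodes[[idx[1]]]$float_index <- nfl + 1L
  system
}

#' Point-source specification
#'
#' @param positions numeric `k` x 3 matrix of monopole positions (m).
#' @param currents numeric vector of monopole currents (A). A nonzero sum
#'   triggers a warning for pure-Neumann problems (no consistent solution).
#' @return object of class `source_spec`.
#' @export
source_spec <- function(positions, currents) {
  positions <- matrix(as.numeric(positions), ncol = 3L)
  stopifnot(nrow(positions) == length(currents))
  structure(list(positions = positions, currents = as.numeric(currents)),
            class = "source_spec")
}

#' Dipole as a pair of opposite monopoles
#'
#' @param position dipole center (m).
#' @param orientation dipole axis (normalized internally).
#' @param current monopole magnitude (A), default 100 uA.
#' @param separation monopole separation (m), default 1 mm.
#' @return a [source_spec()] with two monopoles `+current` and `-current`
#'   at `position +/- separation/2 * orientation`.
#' @export
dipole_source <- function(position, orientation, current = 100e-6,
                          separation = 1e-3) {
  u <- orientation / sqrt(sum(orientation^2))
  source_spec(rbind(position + separation / 2 * u,
                    position - separation / 2 * u),
              c(current, -current))
}

#' Assemble point-source right-hand side
#'
#' Each monopole `(x0, I)` contributes `I N_i(x0)` to the load vector for
#' the basis functions of the cell containing `x0` (barycentric basis
#' evaluation, not nearest-node snapping).
#'
#' @param system a `fem_system`.
#' @param source a [source_spec()] or [dipole_source()].
#' @param locator optional prebuilt [mesh_locator()].
#' @return the updated `fem_system`.
#' @export
assemble_source_rhs <- function(system, source, locator = NULL) {
  stopifnot(inherits(source, "source_spec"))
  if (is.null(locator)) locator <- mesh_locator(system$mesh)
  loc <- locate_points(locator, source$positions)
  if (abs(sum(source$currents)) > 1e-12 * max(abs(source$currents), 1e-300) &&
      !system$has_robin)
    warning("source currents do not sum to zero in a pure-Neumann problem")
  for (k in seq_along(source$currents)) {
    cell <- loc$cell[k]; l <- loc$bary[k, ]
    if (system$dofinfo$order == 1L) {
      dofs <- system$mesh$tets[cell, ]
      vals <- .p1_basis(l)
    } else {
      dofs <- c(system$mesh$tets[cell, ],
                system$dofinfo$nn + system$dofinfo$cell_edges[cell, ])
      vals <- .p2_basis(l)
    }
    system$b_r[dofs] <- system$b_r[dofs] + source$currents[k] * vals
  }
  system
}
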