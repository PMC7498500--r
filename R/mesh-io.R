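## Gmsh MSH 2.2 ASCII input/output. Physical volume tags carry the cell
## markers, physical surface tags the facet markers; $PhysicalNames (if
## present) populates marker_names. Only 4-node tets (type 4) and 3-node
## triangles (type 2) are accepted as elements.

#' Write a mesh to Gmsh MSH 2.2 ASCII
#'
#' @param mesh a [tet_mesh()].
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), con)
  nm <- mesh$marker_names
  if (!is.null(nm) && length(nm)) {
    ## dimension: 3 if a cell marker, 2 otherwise
    dims <- ifelse(nm %in% mesh$cell_markers, 3L, 2L)
    writeLines("$PhysicalNames", con)
    writeLines(as.character(length(nm)), con)
    writeLines(sprintf("%d %d \"%s\"", dims, nm, names(nm)), con)
    writeLines("$EndPhysicalNames", con)
  }
  writeLines("$Nodes", con)
  writeLines(as.character(nrow(mesh$nodes)), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]),
             con)
  writeLines("$EndNodes", con)
  nt <- nrow(mesh$tets); nf <- nrow(mesh$facets)
  writeLines("$Elements", con)
  writeLines(as.character(nt + nf), con)
  if (nf > 0L)
    writeLines(sprintf("%d 2 2 %d %d %d %d %d", seq_len(nf),
                       mesh$facet_markers, mesh$facet_markers,
                       mesh$facets[, 1], mesh$facets[, 2], mesh$facets[, 3]),
               con)
  writeLines(sprintf("%d 4 2 %d %d %d %d %d %d", nf + seq_len(nt),
                     mesh$cell_markers, mesh$cell_markers,
                     mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                     mesh$tets[, 4]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a Gmsh MSH 2.2 ASCII mesh
#'
#' @param path file path.
#' @param validate run [validate_tet_mesh()] on the result.
#' @return a [tet_mesh()].
#' @export
read_msh <- function(path, validate = TRUE) {
  lines <- readLines(path)
  sect <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) return(NULL)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- sect("MeshFormat")
  if (is.null(fmt)) stop("not an MSH file: missing $MeshFormat")
  ver <- strsplit(trimws(fmt[1]), "\\s+")[[1]][1]
  if (!startsWith(ver, "2"))
    stop("unsupported MSH version ", ver, " (need 2.x ASCII)")

  nl <- sect("Nodes")
  nn <- as.integer(nl[1])
  ntab <- matrix(scan(text = nl[-1], quiet = TRUE), ncol = 4L, byrow = TRUE)
  nodes <- matrix(NA_real_, nn, 3L)
  nodes[ntab[, 1], ] <- ntab[, 2:4]

  el <- sect("Elements")
  ne <- as.integer(el[1])
  el <- el[-1]
  tok <- strsplit(el, "\\s+")
  types <- vapply(tok, function(t) as.integer(t[2]), integer(1))
  bad <- setdiff(unique(types), c(2L, 4L, 15L, 1L))
  if (length(bad)) {
    tname <- c("1" = "line", "2" = "triangle", "3" = "quadrangle",
               "4" = "tetrahedron", "5" = "hexahedron", "6" = "prism",
               "7" = "pyramid", "15" = "point")
    stop("unsupported element type(s): ",
         paste(ifelse(as.character(bad) %in% names(tname),
                      tname[as.character(bad)], bad), collapse = ", "))
  }
  get_elem <- function(t, nvert) {
    ntags <- as.integer(t[3])
    phys <- if (ntags >= 1L) as.integer(t[4]) else 0L
    c(phys, as.integer(t[(3L + ntags + 1L):(3L + ntags + nvert)]))
  }
  it <- which(types == 4L)
  if (!length(it)) stop("no tetrahedra in file")
  tt <- t(vapply(tok[it], get_elem, integer(5), nvert = 4L))
  tets <- tt[, 2:5, drop = FALSE]
  cell_markers <- tt[, 1]
  facets <- matrix(integer(0), 0, 3); fmark <- integer(0)
  ifc <- which(types == 2L)
  if (length(ifc)) {
    ft <- t(vapply(tok[ifc], get_elem, integer(4), nvert = 3L))
    facets <- ft[, 2:4, drop = FALSE]
    fmark <- ft[, 1]
  }
  marker_names <- NULL
  pn <- sect("PhysicalNames")
  if (!is.null(pn) && length(pn) > 1L) {
    pn <- pn[-1]
    mm <- regmatches(pn, regexec("^\\s*\\d+\\s+(\\d+)\\s+\"(.*)\"", pn))
    ok <- lengths(mm) == 3L
    marker_names <- setNames(as.integer(vapply(mm[ok], `[`, "", 2L)),
                             vapply(mm[ok], `[`, "", 3L))
  }
  tet_mesh(nodes, tets, cell_markers, facets, fmark, marker_names,
           validate = validate)
}

#' Export a mesh (with optional nodal fields) to legacy ASCII VTK
#'
#' Inspection/visualization plumbing: writes an unstructured-grid `.vtk`
#' file with the subdomain marker as cell data and any supplied nodal
#' fields (real or complex; complex fields are written as `_re`/`_im`
#' pairs) as point data.
#'
#' @param mesh a [tet_mesh()].
#' @param path output path.
#' @param point_fields named list of nodal vectors (length = number of
#'   nodes).
#' @return invisibly `path`.
#' @export
write_vtk <- function(mesh, path, point_fields = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); nt <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", "femvc mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", nn), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nt, nt * 5L), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1L,
                     mesh$tets[, 2] - 1L, mesh$tets[, 3] - 1L,
                     mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(rep("10", nt), con)
  writeLines(sprintf("CELL_DATA %d", nt), con)
  writeLines(c("SCALARS subdomain int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$cell_markers), con)
  if (length(point_fields)) {
    writeLines(sprintf("POINT_DATA %d", nn), con)
    for (nmf in names(point_fields)) {
      f <- point_fields[[nmf]]
      stopifnot(length(f) == nn)
      if (is.complex(f)) {
        for (part in c("re", "im")) {
          vals <- if (part == "re") Re(f) else Im(f)
          writeLines(c(sprintf("SCALARS %s_%s double 1", nmf, part),
                       "LOOKUP_TABLE default"), con)
          writeLines(sprintf("%.17g", vals), con)
        }
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nmf),
                     "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.17g", f), con)
      }
    }
  }
  invisible(path)
}
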