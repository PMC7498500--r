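#' Extract a submesh by cell markers
#'
#' Restricts the mesh to the cells whose subdomain marker is in `keep`,
#' renumbering nodes. Marked facets whose triangle survives are kept with
#' their markers; newly exposed cut surfaces get a fresh facet marker
#' (named `"cut"`).
#'
#' @param mesh a [tet_mesh()].
#' @param keep integer vector of cell markers to retain.
#' @return a [tet_mesh()] with attribute `node_map`: for each node of the
#'   submesh, its index in the parent mesh (`field_sub <- field[node_map]`
#'   transfers nodal fields).
#' @export
extract_submesh <- function(mesh, keep) {
  keep <- as.integer(keep)
  if (length(keep) == 0L) stop("keep must be non-empty")
  if (!all(keep %in% mesh$cell_markers))
    stop("markers not present in mesh: ",
         paste(setdiff(keep, mesh$cell_markers), collapse = ", "))
  sel <- mesh$cell_markers %in% keep
  if (!any(sel)) stop("submesh is empty")
  tets <- mesh$tets[sel, , drop = FALSE]
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(mesh$nodes))
  remap[used] <- seq_along(used)
  new_tets <- matrix(remap[tets], ncol = 4L)
  nodes <- mesh$nodes[used, , drop = FALSE]

  ## surviving marked facets: all 3 nodes used and the face belongs to a
  ## kept tet
  facets <- matrix(integer(0), 0, 3); fmark <- integer(0)
  sub_keys <- tet_face_keys(new_tets)$key
  if (nrow(mesh$facets) > 0L) {
    ok <- rowSums(matrix(remap[mesh$facets] > 0L,
                         nrow(mesh$facets), 3L)) == 3L
    cand <- matrix(remap[mesh$facets[ok, , drop = FALSE]], ncol = 3L)
    cm <- mesh$facet_markers[ok]
    present <- face_key(cand) %in% sub_keys
    facets <- cand[present, , drop = FALSE]
    fmark <- cm[present]
  }
  ## new exterior (cut) faces: boundary faces not already marked
  sub <- tet_mesh(nodes, new_tets, mesh$cell_markers[sel],
                  validate = FALSE)
  bf <- boundary_faces(sub)
  if (nrow(bf) > 0L) {
    already <- if (nrow(facets)) face_key(bf) %in% face_key(facets)
               else rep(FALSE, nrow(bf))
    cut <- bf[!already, , drop = FALSE]
    if (nrow(cut)) {
      cut_id <- max(c(mesh$cell_markers, mesh$facet_markers, 0L)) + 1L
      facets <- rbind(facets, cut)
      fmark <- c(fmark, rep.int(cut_id, nrow(cut)))
      mesh$marker_names <- c(mesh$marker_names, setNames(cut_id, "cut"))
    }
  }
  out <- tet_mesh(nodes, new_tets, mesh$cell_markers[sel], facets, fmark,
                  mesh$marker_names, validate = FALSE)
  attr(out, "node_map") <- used
  out
}
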