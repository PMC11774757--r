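# Submesh views and surface adjacency.
#
# A submesh view realizes one tagged compartment as a local entity/vertex
# numbering plus maps back to the parent mesh; compartments never copy
# coordinates, they index into the parent.

#' Extract the submesh view of a tagged compartment
#'
#' @param mesh a `parent_mesh`.
#' @param tag integer tag (or name hint).
#' @param dim `"cell"` for a volume compartment (dimension d) or `"facet"`
#'   for a surface compartment (dimension d-1).
#' @return an object of class `submesh_view` with fields `entities` (local
#'   entity matrix over local vertex indices), `vertex_parent` (local ->
#'   parent vertex map), `entity_parent` (local -> parent entity map),
#'   `measures`, `dim_kind`, and the owning mesh.
#' @export
extract_submesh <- function(mesh, tag, dim = c("cell", "facet")) {
  dim <- match.arg(dim)
  tag <- resolve_tag(mesh, tag, dim)
  tags <- if (dim == "cell") mesh$cell_tags else mesh$facet_tags
  if (!any(tags == tag)) {
    avail <- sort(unique(tags))
    stop(sprintf("unknown %s tag %d; available tags: %s", dim, tag,
                 paste(avail, collapse = ", ")), call. = FALSE)
  }
  sel <- which(tags == tag)
  ents <- if (dim == "cell") mesh$cells[sel, , drop = FALSE]
          else mesh$facets[sel, , drop = FALSE]
  vp <- sort(unique(as.vector(ents)))
  local_of <- integer(nrow(mesh$vertices))
  local_of[vp] <- seq_along(vp)
  local_ents <- matrix(local_of[ents], nrow = nrow(ents))
  measures <- if (dim == "cell") mesh$cell_measures[sel] else mesh$facet_measures[sel]
  structure(list(
    mesh = mesh,
    tag = tag,
    dim_kind = dim,
    entities = local_ents,
    vertex_parent = vp,
    entity_parent = sel,
    measures = measures,
    n_vertices = length(vp)
  ), class = "submesh_view")
}

#' @export
print.submesh_view <- function(x, ...) {
  cat(sprintf("<submesh_view: tag %d (%s), %d entities, %d vertices, measure %.6g>\n",
              x$tag, x$dim_kind, nrow(x$entities), x$n_vertices, sum(x$measures)))
  invisible(x)
}

# local coordinates of a submesh view
submesh_coords <- function(sub) {
  sub$mesh$vertices[sub$vertex_parent, , drop = FALSE]
}

#' Bordering volumes and side-resolved normals of a surface
#'
#' For a tagged surface, reports the volume compartments it borders (one for
#' an exterior boundary, two for an interior interface) and, per facet, the
#' outward unit normal of each bordering side.  Side order follows the
#' returned `volumes` vector (ascending volume tag); the positive flux
#' direction used elsewhere is outward from the first-listed volume.
#'
#' @param mesh a `parent_mesh`.
#' @param surface_tag integer facet tag (or name hint).
#' @return list with `volumes` (bordering volume tags), `facets` (parent
#'   facet indices), `cells` (facet x side matrix of parent cells, ordered
#'   like `volumes`), `normals` (list, one (nf x d) matrix per side, outward
#'   from that side's volume).
#' @export
surface_adjacency <- function(mesh, surface_tag) {
  surface_tag <- resolve_tag(mesh, surface_tag, "facet")
  sel <- which(mesh$facet_tags == surface_tag)
  if (!length(sel)) {
    stop(sprintf("unknown surface tag %d; available: %s", surface_tag,
                 paste(sort(unique(mesh$facet_tags)), collapse = ", ")),
         call. = FALSE)
  }
  c1 <- mesh$facet_cells[sel, 1L]
  c2 <- mesh$facet_cells[sel, 2L]
  t1 <- mesh$cell_tags[c1]
  t2 <- ifelse(is.na(c2), NA_integer_, mesh$cell_tags[c2])
  interior <- !is.na(c2)
  if (any(interior) && any(!interior)) {
    stop(sprintf("mesh consistency error: surface tag %d mixes exterior and interior facets",
                 surface_tag), call. = FALSE)
  }
  if (!any(interior)) {
    vols <- sort(unique(t1))
    if (length(vols) != 1L) {
      stop(sprintf("mesh consistency error: exterior surface %d borders multiple volume tags (%s)",
                   surface_tag, paste(vols, collapse = ", ")), call. = FALSE)
    }
    return(list(volumes = vols, facets = sel,
                cells = matrix(c1, ncol = 1L),
                normals = list(mesh$facet_normal1[sel, , drop = FALSE])))
  }
  pair <- unique(cbind(pmin(t1, t2), pmax(t1, t2)))
  if (nrow(pair) != 1L) {
    stop(sprintf("mesh consistency error: interior surface %d borders inconsistent volume pairs",
                 surface_tag), call. = FALSE)
  }
  if (pair[1, 1] == pair[1, 2]) {
    vols <- pair[1, 1]  # declared internal membrane inside one volume
    return(list(volumes = vols, facets = sel,
                cells = cbind(c1, c2),
                normals = list(mesh$facet_normal1[sel, , drop = FALSE],
                               mesh$facet_normal2[sel, , drop = FALSE])))
  }
  vols <- as.integer(pair[1, ])
  # align side 1 with vols[1]
  swap <- t1 != vols[1]
  cells <- cbind(ifelse(swap, c2, c1), ifelse(swap, c1, c2))
  n1 <- mesh$facet_normal1[sel, , drop = FALSE]
  n2 <- mesh$facet_normal2[sel, , drop = FALSE]
  nn1 <- n1; nn2 <- n2
  nn1[swap, ] <- n2[swap, , drop = FALSE]
  nn2[swap, ] <- n1[swap, , drop = FALSE]
  list(volumes = vols, facets = sel, cells = cells, normals = list(nn1, nn2))
}

#' Summarize a mesh: tags, entity counts, measures
#'
#' The `describe` entry point: prints per-tag entity counts and measures,
#' and returns them invisibly as a data frame.
#' @param mesh a `parent_mesh`.
#' @export
describe_mesh <- function(mesh) {
  rows <- list()
  for (tg in sort(unique(mesh$cell_tags))) {
    nm <- mesh$cell_tag_names[[as.character(tg)]]
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "volume", tag = tg, name = if (is.null(nm)) NA_character_ else nm,
      entities = sum(mesh$cell_tags == tg),
      measure = sum(mesh$cell_measures[mesh$cell_tags == tg]))
  }
  for (tg in sort(unique(mesh$facet_tags))) {
    nm <- mesh$facet_tag_names[[as.character(tg)]]
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "surface", tag = tg, name = if (is.null(nm)) NA_character_ else nm,
      entities = sum(mesh$facet_tags == tg),
      measure = sum(mesh$facet_measures[mesh$facet_tags == tg]))
  }
  df <- do.call(rbind, rows)
  print(mesh)
  invisible(df)
}
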