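# The tagged simplicial parent mesh.
#
# All geometry lives on one parent mesh: volume compartments are sets of
# d-cells sharing an integer tag, membranes are sets of (d-1)-facets sharing
# a tag.  Vertex and cell indices are 1-based (R convention).  Cells are
# stored with positive orientation (positive signed measure); facet normals
# are precomputed per incident side, outward from that side's cell.

.face_key <- function(idx_matrix) {
  apply(idx_matrix, 1L, function(v) paste(sort(v), collapse = "_"))
}

# faces of each cell: for a d-simplex, the d+1 faces obtained by dropping one
# vertex.  Returns a matrix with one face per row plus the owning cell index.
.cell_faces <- function(cells) {
  nv <- ncol(cells)
  nc <- nrow(cells)
  faces <- vector("list", nv)
  for (drop in seq_len(nv)) {
    faces[[drop]] <- cells[, -drop, drop = FALSE]
  }
  list(faces = do.call(rbind, faces),
       cell = rep(seq_len(nc), times = nv))
}

.signed_measure <- function(vertices, cells) {
  d <- ncol(vertices)
  if (d == 3L) {
    a <- vertices[cells[, 2], , drop = FALSE] - vertices[cells[, 1], , drop = FALSE]
    b <- vertices[cells[, 3], , drop = FALSE] - vertices[cells[, 1], , drop = FALSE]
    c <- vertices[cells[, 4], , drop = FALSE] - vertices[cells[, 1], , drop = FALSE]
    det3 <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
            a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
            a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
    det3 / 6
  } else {
    a <- vertices[cells[, 2], , drop = FALSE] - vertices[cells[, 1], , drop = FALSE]
    b <- vertices[cells[, 3], , drop = FALSE] - vertices[cells[, 1], , drop = FALSE]
    (a[, 1] * b[, 2] - a[, 2] * b[, 1]) / 2
  }
}

# unsigned measure of (d-1)-simplices embedded in d dimensions
.facet_measure <- function(vertices, facets) {
  d <- ncol(vertices)
  if (d == 3L) {
    a <- vertices[facets[, 2], , drop = FALSE] - vertices[facets[, 1], , drop = FALSE]
    b <- vertices[facets[, 3], , drop = FALSE] - vertices[facets[, 1], , drop = FALSE]
    cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
    cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
    cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
    sqrt(cx^2 + cy^2 + cz^2) / 2
  } else {
    a <- vertices[facets[, 2], , drop = FALSE] - vertices[facets[, 1], , drop = FALSE]
    sqrt(rowSums(a^2))
  }
}

# outward unit normal of each facet with respect to a given incident cell:
# points away from the vertex of the cell opposite to the facet
.facet_normal_outward <- function(vertices, facets, cells, cell_of) {
  d <- ncol(vertices)
  n <- matrix(0, nrow(facets), d)
  if (d == 3L) {
    a <- vertices[facets[, 2], , drop = FALSE] - vertices[facets[, 1], , drop = FALSE]
    b <- vertices[facets[, 3], , drop = FALSE] - vertices[facets[, 1], , drop = FALSE]
    n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  } else {
    a <- vertices[facets[, 2], , drop = FALSE] - vertices[facets[, 1], , drop = FALSE]
    n <- cbind(a[, 2], -a[, 1])
  }
  n <- n / sqrt(rowSums(n^2))
  # opposite vertex: the cell vertex not on the facet
  for (i in seq_len(nrow(facets))) {
    cv <- cells[cell_of[i], ]
    opp <- setdiff(cv, facets[i, ])[1]
    w <- vertices[opp, ] - vertices[facets[i, 1], ]
    if (sum(n[i, ] * w) > 0) n[i, ] <- -n[i, ]
  }
  n
}

#' Construct a tagged simplicial parent mesh
#'
#' Builds the single mesh that carries all compartments: tagged d-cells
#' define volume subdomains, tagged (d-1)-facets define membranes
#' (exterior boundaries or interior interfaces).  Cells are reoriented to
#' positive signed measure; facet-to-cell adjacency and side-resolved
#' outward normals are precomputed.
#'
#' @param vertices numeric matrix (n x d), coordinates in micrometres,
#'   d = 2 or 3.
#' @param cells integer matrix (nc x (d+1)) of 1-based vertex indices.
#' @param cell_tags integer vector, one tag per cell.
#' @param facets integer matrix (nf x d) of tagged facets (1-based vertex
#'   indices); each must be a face of at least one cell.
#' @param facet_tags integer vector, one tag per tagged facet.
#' @param cell_tag_names,facet_tag_names optional named character vectors
#'   mapping tag id (as name) to a compartment-name hint.
#' @param internal_membranes integer vector of facet tags that are allowed
#'   to separate cells carrying the same volume tag.  By default an interior
#'   facet between like-tagged cells is rejected as a probable tagging
#'   mistake.
#' @return an object of class `parent_mesh`.
#' @export
parent_mesh <- function(vertices, cells, cell_tags, facets, facet_tags,
                        cell_tag_names = NULL, facet_tag_names = NULL,
                        internal_membranes = integer()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  facets <- as.matrix(facets)
  storage.mode(facets) <- "integer"
  d <- ncol(vertices)
  if (!d %in% c(2L, 3L)) stop("mesh dimension must be 2 or 3", call. = FALSE)
  if (ncol(cells) != d + 1L) stop("cells must be d-simplices", call. = FALSE)
  if (ncol(facets) != d) stop("facets must be (d-1)-simplices", call. = FALSE)
  if (any(!is.finite(vertices))) {
    stop("geometry error: non-finite vertex coordinates", call. = FALSE)
  }
  if (length(cell_tags) != nrow(cells)) {
    stop("cell_tags length must match cell count", call. = FALSE)
  }
  if (length(facet_tags) != nrow(facets)) {
    stop("facet_tags length must match facet count", call. = FALSE)
  }
  bbox_scale <- max(apply(vertices, 2, function(v) diff(range(v))), 1e-300)

  # orient cells positively
  sm <- .signed_measure(vertices, cells)
  flip <- which(sm < 0)
  if (length(flip)) {
    tmp <- cells[flip, 1L]
    cells[flip, 1L] <- cells[flip, 2L]
    cells[flip, 2L] <- tmp
    sm[flip] <- -sm[flip]
  }
  tol_cell <- 1e-12 * bbox_scale^d
  if (any(sm <= tol_cell)) {
    bad <- which(sm <= tol_cell)[1]
    stop(sprintf("geometry error: degenerate cell %d (measure %.3e)",
                 bad, sm[bad]), call. = FALSE)
  }
  fm <- .facet_measure(vertices, facets)
  tol_facet <- 1e-12 * bbox_scale^(d - 1L)
  if (nrow(facets) && any(fm <= tol_facet)) {
    bad <- which(fm <= tol_facet)[1]
    stop(sprintf("geometry error: degenerate facet %d (measure %.3e)",
                 bad, fm[bad]), call. = FALSE)
  }

  # facet -> incident cells via face matching
  cf <- .cell_faces(cells)
  fk <- .face_key(cf$faces)
  tk <- if (nrow(facets)) .face_key(facets) else character()
  incid <- split(cf$cell, fk)
  facet_cells <- matrix(NA_integer_, nrow(facets), 2L)
  for (i in seq_len(nrow(facets))) {
    inc <- incid[[tk[i]]]
    if (is.null(inc)) {
      stop(sprintf("mesh consistency error: tagged facet %d is not a face of any cell", i),
           call. = FALSE)
    }
    if (length(inc) > 2L) {
      stop(sprintf("mesh consistency error: facet %d bordered by %d cells",
                   i, length(inc)), call. = FALSE)
    }
    facet_cells[i, seq_along(inc)] <- sort(inc)
  }
  # interior facets between like-tagged cells are suspicious unless declared
  interior <- !is.na(facet_cells[, 2L])
  if (any(interior)) {
    same <- interior &
      cell_tags[facet_cells[, 1L]] == cell_tags[ifelse(interior, facet_cells[, 2L], 1L)]
    offending <- same & !(facet_tags %in% internal_membranes)
    if (any(offending)) {
      i <- which(offending)[1]
      stop(sprintf(paste("mesh consistency error: interior facet %d (tag %d) separates",
                         "two cells with the same volume tag %d; declare it in",
                         "internal_membranes if intended"),
                   i, facet_tags[i], cell_tags[facet_cells[i, 1L]]), call. = FALSE)
    }
  }
  normal1 <- if (nrow(facets)) {
    .facet_normal_outward(vertices, facets, cells, facet_cells[, 1L])
  } else matrix(0, 0, d)
  normal2 <- -normal1
  normal2[!interior, ] <- NA_real_

  structure(list(
    dim = d,
    vertices = vertices,
    cells = cells,
    cell_tags = as.integer(cell_tags),
    facets = facets,
    facet_tags = as.integer(facet_tags),
    facet_cells = facet_cells,
    facet_normal1 = normal1,
    facet_normal2 = normal2,
    cell_measures = sm,
    facet_measures = fm,
    cell_tag_names = cell_tag_names,
    facet_tag_names = facet_tag_names,
    internal_membranes = as.integer(internal_membranes)
  ), class = "parent_mesh")
}

#' @export
print.parent_mesh <- function(x, ...) {
  cat(sprintf("<parent_mesh: dim %d, %d vertices, %d cells, %d tagged facets>\n",
              x$dim, nrow(x$vertices), nrow(x$cells), nrow(x$facets)))
  for (tg in sort(unique(x$cell_tags))) {
    nm <- x$cell_tag_names[[as.character(tg)]]
    cat(sprintf("  volume tag %d%s: %d cells, measure %.6g\n", tg,
                if (is.null(nm)) "" else paste0(" (", nm, ")"),
                sum(x$cell_tags == tg), sum(x$cell_measures[x$cell_tags == tg])))
  }
  for (tg in sort(unique(x$facet_tags))) {
    nm <- x$facet_tag_names[[as.character(tg)]]
    cat(sprintf("  surface tag %d%s: %d facets, measure %.6g\n", tg,
                if (is.null(nm)) "" else paste0(" (", nm, ")"),
                sum(x$facet_tags == tg), sum(x$facet_measures[x$facet_tags == tg])))
  }
  invisible(x)
}

#' Total measure of a tagged region
#'
#' Sum of cell measures (volume tag) or facet measures (surface tag).
#' @param mesh a `parent_mesh`.
#' @param tag integer tag.
#' @param dim `"cell"` or `"facet"`.
#' @export
tag_measure <- function(mesh, tag, dim = c("cell", "facet")) {
  dim <- match.arg(dim)
  if (dim == "cell") {
    sum(mesh$cell_measures[mesh$cell_tags == tag])
  } else {
    sum(mesh$facet_measures[mesh$facet_tags == tag])
  }
}

# tag id for a name hint (or the tag itself if numeric)
resolve_tag <- function(mesh, tag, what = c("cell", "facet")) {
  what <- match.arg(what)
  names_map <- if (what == "cell") mesh$cell_tag_names else mesh$facet_tag_names
  if (is.character(tag)) {
    hit <- names(names_map)[match(tag, unlist(names_map))]
    if (is.na(hit) || is.null(hit)) {
      stop(sprintf("unknown %s tag name '%s'; available: %s", what, tag,
                   paste(unlist(names_map), collapse = ", ")), call. = FALSE)
    }
    return(as.integer(hit))
  }
  as.integer(tag)
}
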