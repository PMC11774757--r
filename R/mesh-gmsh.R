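# Gmsh MSH 4.1 ASCII I/O and legacy VTK output.
#
# Only the 4.1 ASCII dialect is read: physical-group integer ids become
# tags, physical-group names become compartment-name hints.  Older headers
# (2.2) are rejected outright.  Writing emits one discrete entity per
# physical group, which Gmsh itself reads back.

.msh_section <- function(lines, name) {
  i0 <- which(lines == paste0("$", name))
  i1 <- which(lines == paste0("$End", name))
  if (!length(i0) || !length(i1)) return(NULL)
  lines[(i0[1] + 1L):(i1[1] - 1L)]
}

.split_nums <- function(line) {
  as.numeric(strsplit(trimws(line), "\\s+")[[1]])
}

#' Read a tagged mesh from a Gmsh MSH 4.1 ASCII file
#'
#' Physical-group ids of dimension d become volume (cell) tags and those of
#' dimension d-1 become surface (facet) tags; physical names, if present,
#' become name hints.  Elements belonging to entities without a physical
#' group are ignored for tagging but volume cells are always retained.
#'
#' @param path path to a `.msh` file (MSH 4.1 ASCII).
#' @param internal_membranes facet tags allowed between like-tagged cells
#'   (see [parent_mesh()]).
#' @return a `parent_mesh`.
#' @export
load_gmsh <- function(path, internal_membranes = integer()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  fmt <- .msh_section(lines, "MeshFormat")
  if (is.null(fmt)) stop("format error: missing $MeshFormat section", call. = FALSE)
  ver <- .split_nums(fmt[1])
  if (abs(ver[1] - 4.1) > 1e-9) {
    stop(sprintf("format error: MSH version %.1f not supported (need 4.1 ASCII)",
                 ver[1]), call. = FALSE)
  }
  if (ver[2] != 0) stop("format error: binary MSH not supported", call. = FALSE)

  # physical names (optional)
  pn <- .msh_section(lines, "PhysicalNames")
  phys_names <- list()
  if (!is.null(pn)) {
    for (ln in pn[-1]) {
      m <- regmatches(ln, regexec('^\\s*(\\d+)\\s+(\\d+)\\s+"(.*)"', ln))[[1]]
      if (length(m)) {
        phys_names[[paste(m[2], m[3], sep = ":")]] <- m[4]
      }
    }
  }

  # entities: map (dim, entityTag) -> physical tag (first listed)
  ent <- .msh_section(lines, "Entities")
  if (is.null(ent)) stop("format error: missing $Entities section", call. = FALSE)
  counts <- .split_nums(ent[1])
  ent_phys <- new.env(hash = TRUE)
  row <- 2L
  for (dm in 0:3) {
    for (k in seq_len(counts[dm + 1L])) {
      v <- .split_nums(ent[row]); row <- row + 1L
      # point entities: tag x y z numPhys ...; others: tag 6 bbox values
      if (dm == 0L) {
        nphys <- v[5]
        phys <- if (nphys > 0) v[6] else NA_real_
      } else {
        nphys <- v[8]
        phys <- if (nphys > 0) v[9] else NA_real_
      }
      if (!is.na(phys)) {
        ent_phys[[paste(dm, as.integer(v[1]))]] <- as.integer(phys)
      }
    }
  }

  # nodes
  nd <- .msh_section(lines, "Nodes")
  if (is.null(nd)) stop("format error: missing $Nodes section", call. = FALSE)
  hdr <- .split_nums(nd[1])
  n_blocks <- hdr[1]; n_nodes <- hdr[2]
  coords <- matrix(NA_real_, n_nodes, 3L)
  node_id <- integer(n_nodes)
  row <- 2L; got <- 0L
  for (b in seq_len(n_blocks)) {
    bh <- .split_nums(nd[row]); row <- row + 1L
    nb <- bh[4]
    if (nb == 0) next
    ids <- vapply(nd[row:(row + nb - 1L)], function(s) as.integer(s), 1L,
                  USE.NAMES = FALSE)
    row <- row + nb
    for (k in seq_len(nb)) {
      coords[got + k, ] <- .split_nums(nd[row]); row <- row + 1L
    }
    node_id[got + seq_len(nb)] <- ids
    got <- got + nb
  }
  remap <- integer(max(node_id))
  remap[node_id] <- seq_len(n_nodes)

  # elements
  el <- .msh_section(lines, "Elements")
  if (is.null(el)) stop("format error: missing $Elements section", call. = FALSE)
  hdr <- .split_nums(el[1])
  n_blocks <- hdr[1]
  tets <- list(); tris <- list(); segs <- list()
  tet_phys <- list(); tri_phys <- list(); seg_phys <- list()
  row <- 2L
  for (b in seq_len(n_blocks)) {
    bh <- .split_nums(el[row]); row <- row + 1L
    edim <- bh[1]; etag <- bh[2]; etype <- bh[3]; ne <- bh[4]
    if (ne == 0) next
    block <- el[row:(row + ne - 1L)]; row <- row + ne
    phys <- ent_phys[[paste(edim, as.integer(etag))]]
    dat <- t(vapply(block, .split_nums, numeric(if (etype == 4) 5 else if (etype == 2) 4 else if (etype == 1) 3 else length(.split_nums(block[1]))), USE.NAMES = FALSE))
    conn <- matrix(remap[as.integer(dat[, -1, drop = FALSE])], nrow = ne)
    if (etype == 4) {        # 4-node tetrahedron
      tets[[length(tets) + 1L]] <- conn
      tet_phys[[length(tet_phys) + 1L]] <- rep(if (is.null(phys)) NA_integer_ else phys, ne)
    } else if (etype == 2) { # 3-node triangle
      tris[[length(tris) + 1L]] <- conn
      tri_phys[[length(tri_phys) + 1L]] <- rep(if (is.null(phys)) NA_integer_ else phys, ne)
    } else if (etype == 1) { # 2-node line
      segs[[length(segs) + 1L]] <- conn
      seg_phys[[length(seg_phys) + 1L]] <- rep(if (is.null(phys)) NA_integer_ else phys, ne)
    }                        # points and higher-order elements ignored
  }
  has_tets <- length(tets) > 0L
  if (has_tets) {
    d <- 3L
    cells <- do.call(rbind, tets); cell_phys <- unlist(tet_phys)
    facets <- if (length(tris)) do.call(rbind, tris) else matrix(0L, 0, 3)
    facet_phys <- unlist(tri_phys)
  } else if (length(tris)) {
    d <- 2L
    cells <- do.call(rbind, tris); cell_phys <- unlist(tri_phys)
    facets <- if (length(segs)) do.call(rbind, segs) else matrix(0L, 0, 2)
    facet_phys <- unlist(seg_phys)
  } else {
    stop("model error: no volume elements (tetrahedra or triangles) in file",
         call. = FALSE)
  }
  if (all(is.na(cell_phys))) {
    stop("model error: no physical group of the volume dimension", call. = FALSE)
  }
  keep <- !is.na(facet_phys)
  if (!any(keep)) {
    stop("model error: no physical group of the surface dimension", call. = FALSE)
  }
  facets <- facets[keep, , drop = FALSE]
  facet_phys <- facet_phys[keep]
  if (any(is.na(cell_phys))) {
    stop("model error: volume elements without a physical group", call. = FALSE)
  }
  verts <- coords[, seq_len(d), drop = FALSE]
  if (d == 2L && any(abs(coords[, 3]) > 1e-9 * max(abs(coords)))) {
    stop("geometry error: triangle mesh is not planar in z = 0", call. = FALSE)
  }
  cn <- list(); fn <- list()
  for (key in names(phys_names)) {
    kv <- strsplit(key, ":")[[1]]
    if (as.integer(kv[1]) == d) cn[[kv[2]]] <- phys_names[[key]]
    if (as.integer(kv[1]) == d - 1L) fn[[kv[2]]] <- phys_names[[key]]
  }
  parent_mesh(verts, cells, cell_phys, facets, facet_phys,
              cell_tag_names = if (length(cn)) cn else NULL,
              facet_tag_names = if (length(fn)) fn else NULL,
              internal_membranes = internal_membranes)
}

#' Write a parent mesh as Gmsh MSH 4.1 ASCII
#'
#' Emits one discrete entity per tag (volume tags as dim-d entities, facet
#' tags as dim-(d-1) entities), each bound to a physical group of the same
#' id; names, when present, go to `$PhysicalNames`.
#'
#' @param mesh a `parent_mesh`.
#' @param path output file path.
#' @export
write_gmsh <- function(mesh, path) {
  d <- mesh$dim
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("$MeshFormat"); w("4.1 0 8"); w("$EndMeshFormat")

  vol_tags <- sort(unique(mesh$cell_tags))
  fac_tags <- sort(unique(mesh$facet_tags))
  names_all <- c(
    lapply(fac_tags, function(tg) {
      nm <- mesh$facet_tag_names[[as.character(tg)]]
      if (is.null(nm)) NULL else sprintf('%d %d "%s"', d - 1L, tg, nm)
    }),
    lapply(vol_tags, function(tg) {
      nm <- mesh$cell_tag_names[[as.character(tg)]]
      if (is.null(nm)) NULL else sprintf('%d %d "%s"', d, tg, nm)
    }))
  names_all <- Filter(Negate(is.null), names_all)
  if (length(names_all)) {
    w("$PhysicalNames"); w("%d", length(names_all))
    for (ln in names_all) writeLines(ln, con)
    w("$EndPhysicalNames")
  }

  bb <- apply(mesh$vertices, 2, range)
  bb3 <- cbind(bb, matrix(0, 2, 3 - d))
  ent_line <- function(tg) {
    sprintf("%d %.16g %.16g %.16g %.16g %.16g %.16g 1 %d 0",
            tg, bb3[1, 1], bb3[1, 2], bb3[1, 3], bb3[2, 1], bb3[2, 2], bb3[2, 3], tg)
  }
  w("$Entities")
  n_curves <- if (d == 2L) length(fac_tags) else 0L
  n_surfs <- if (d == 2L) length(vol_tags) else length(fac_tags)
  n_vols <- if (d == 3L) length(vol_tags) else 0L
  w("0 %d %d %d", n_curves, n_surfs, n_vols)
  if (d == 2L) {
    for (tg in fac_tags) writeLines(ent_line(tg), con)
    for (tg in vol_tags) writeLines(ent_line(tg), con)
  } else {
    for (tg in fac_tags) writeLines(ent_line(tg), con)
    for (tg in vol_tags) writeLines(ent_line(tg), con)
  }
  w("$EndEntities")

  nv <- nrow(mesh$vertices)
  v3 <- cbind(mesh$vertices, matrix(0, nv, 3 - d))
  w("$Nodes")
  # single block attached to the first volume entity
  w("1 %d 1 %d", nv, nv)
  w("%d %d 0 %d", d, vol_tags[1], nv)
  writeLines(sprintf("%d", seq_len(nv)), con)
  writeLines(sprintf("%.16g %.16g %.16g", v3[, 1], v3[, 2], v3[, 3]), con)
  w("$EndNodes")

  etype_cell <- if (d == 3L) 4L else 2L
  etype_facet <- if (d == 3L) 2L else 1L
  blocks <- list()
  eid <- 0L
  fmt_conn <- function(idm, start) {
    n <- nrow(idm)
    ids <- start + seq_len(n)
    apply(cbind(ids, idm), 1, paste, collapse = " ")
  }
  lines_out <- character()
  n_total <- 0L
  for (tg in fac_tags) {
    sel <- which(mesh$facet_tags == tg)
    lines_out <- c(lines_out,
                   sprintf("%d %d %d %d", d - 1L, tg, etype_facet, length(sel)),
                   fmt_conn(mesh$facets[sel, , drop = FALSE], n_total))
    n_total <- n_total + length(sel)
  }
  for (tg in vol_tags) {
    sel <- which(mesh$cell_tags == tg)
    lines_out <- c(lines_out,
                   sprintf("%d %d %d %d", d, tg, etype_cell, length(sel)),
                   fmt_conn(mesh$cells[sel, , drop = FALSE], n_total))
    n_total <- n_total + length(sel)
  }
  w("$Elements")
  w("%d %d 1 %d", length(fac_tags) + length(vol_tags), n_total, n_total)
  writeLines(lines_out, con)
  w("$EndElements")
  invisible(path)
}

#' Write a legacy-VTK snapshot of a mesh and nodal fields
#'
#' ASCII legacy VTK unstructured grid with optional point-data fields, for
#' inspection in standard VTK viewers.
#'
#' @param mesh a `parent_mesh`.
#' @param path output `.vtk` path.
#' @param point_data named list of numeric vectors (one value per mesh
#'   vertex); `NA` is written for vertices outside a field's compartment.
#' @export
write_vtk <- function(mesh, path, point_data = list()) {
  d <- mesh$dim
  nv <- nrow(mesh$vertices)
  nc <- nrow(mesh$cells)
  v3 <- cbind(mesh$vertices, matrix(0, nv, 3 - d))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("rdmix mesh snapshot")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", nv)
  writeLines(sprintf("%.17g %.17g %.17g", v3[, 1], v3[, 2], v3[, 3]), con)
  nper <- d + 1L
  w("CELLS %d %d", nc, nc * (nper + 1L))
  writeLines(apply(cbind(nper, mesh$cells - 1L), 1, paste, collapse = " "), con)
  w("CELL_TYPES %d", nc)
  writeLines(rep(if (d == 3L) "10" else "5", nc), con)
  w("CELL_DATA %d", nc)
  w("SCALARS tag int 1"); w("LOOKUP_TABLE default")
  writeLines(sprintf("%d", mesh$cell_tags), con)
  if (length(point_data)) {
    w("POINT_DATA %d", nv)
    for (nm in names(point_data)) {
      w("SCALARS %s double 1", nm); w("LOOKUP_TABLE default")
      vals <- point_data[[nm]]
      vals[is.na(vals)] <- -1e30
      writeLines(sprintf("%.17g", vals), con)
    }
  }
  invisible(path)
}
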