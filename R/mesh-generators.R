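# Synthetic geometry generators.
#
# These stand in for microscopy-derived cell geometries: a structured
# tetrahedral slab (membrane on one face), a structured 2D rectangle (used
# for axisymmetric half-sections), and nested spheres/disks emulating a cell
# with one organelle.  All generators emit a fully tagged parent mesh.

#' Structured tetrahedral slab with a membrane face
#'
#' Generates an `n x n x n` structured grid of boxes over
#' `[0,Lx] x [0,Ly] x [0,Lz]`, each split into 6 tetrahedra (Kuhn
#' subdivision, conforming across boxes).  One volume tag (1, "cytosol");
#' the z = 0 face is tagged 2 ("membrane") and every other exterior face is
#' tagged 3 ("no_flux").
#'
#' @param Lx,Ly,Lz slab dimensions in micrometres.
#' @param n number of boxes per edge (>= 1).
#' @return a `parent_mesh`.
#' @export
generate_slab <- function(Lx, Ly, Lz, n) {
  if (!(Lx > 0 && Ly > 0 && Lz > 0)) {
    stop("slab dimensions must be positive", call. = FALSE)
  }
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  m <- n + 1L
  xs <- seq(0, Lx, length.out = m)
  ys <- seq(0, Ly, length.out = m)
  zs <- seq(0, Lz, length.out = m)
  # vertex index (i,j,k) -> linear, i fastest
  vid <- function(i, j, k) i + (j - 1L) * m + (k - 1L) * m * m
  g <- expand.grid(x = xs, y = ys, z = zs)
  vertices <- as.matrix(g)

  # Kuhn subdivision of each box: 6 tets along vertex-permutation paths
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  e <- diag(3L)
  boxes <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  nb <- nrow(boxes)
  cells <- matrix(0L, nb * 6L, 4L)
  row <- 0L
  corner_id <- function(off) vid(boxes$i + off[1], boxes$j + off[2], boxes$k + off[3])
  for (p in perms) {
    o0 <- c(0L, 0L, 0L)
    o1 <- e[p[1], ]
    o2 <- e[p[1], ] + e[p[2], ]
    o3 <- c(1L, 1L, 1L)
    idx <- cbind(corner_id(o0), corner_id(o1), corner_id(o2), corner_id(o3))
    cells[row + seq_len(nb), ] <- idx
    row <- row + nb
  }

  # boundary faces: faces incident to exactly one cell
  cf <- .cell_faces(cells)
  fk <- .face_key(cf$faces)
  cnt <- table(fk)
  bnd <- which(cnt[fk] == 1L)
  bfaces <- cf$faces[bnd, , drop = FALSE]
  zc <- (vertices[bfaces[, 1], 3] + vertices[bfaces[, 2], 3] + vertices[bfaces[, 3], 3]) / 3
  tol <- 1e-9 * max(Lx, Ly, Lz)
  on_membrane <- abs(zc) < tol &
    abs(vertices[bfaces[, 1], 3]) < tol &
    abs(vertices[bfaces[, 2], 3]) < tol &
    abs(vertices[bfaces[, 3], 3]) < tol
  facet_tags <- ifelse(on_membrane, 2L, 3L)

  parent_mesh(vertices, cells,
              cell_tags = rep(1L, nrow(cells)),
              facets = bfaces, facet_tags = facet_tags,
              cell_tag_names = list(`1` = "cytosol"),
              facet_tag_names = list(`2` = "membrane", `3` = "no_flux"))
}

#' Structured triangular rectangle mesh
#'
#' 2D analogue of [generate_slab()]: an `nx x ny` grid of boxes over
#' `[0,Lx] x [0,Ly]`, each split into two triangles.  One volume tag (1,
#' "domain"); boundary edges tagged 2/3/4/5 for left (x=0), right (x=Lx),
#' bottom (y=0) and top (y=Ly).  Useful for axisymmetric (r,z) half-sections
#' with x read as the radial coordinate.
#'
#' @param Lx,Ly rectangle dimensions (micrometres).
#' @param nx,ny boxes per edge (ny defaults to nx).
#' @return a `parent_mesh`.
#' @export
generate_rect <- function(Lx, Ly, nx, ny = nx) {
  if (!(Lx > 0 && Ly > 0)) stop("rectangle dimensions must be positive", call. = FALSE)
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 1L || ny < 1L) stop("nx, ny must be >= 1", call. = FALSE)
  mx <- nx + 1L
  xs <- seq(0, Lx, length.out = mx)
  ys <- seq(0, Ly, length.out = ny + 1L)
  g <- expand.grid(x = xs, y = ys)
  vertices <- as.matrix(g)
  vid <- function(i, j) i + (j - 1L) * mx
  boxes <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  v00 <- vid(boxes$i, boxes$j); v10 <- vid(boxes$i + 1L, boxes$j)
  v01 <- vid(boxes$i, boxes$j + 1L); v11 <- vid(boxes$i + 1L, boxes$j + 1L)
  cells <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  cf <- .cell_faces(cells)
  fk <- .face_key(cf$faces)
  cnt <- table(fk)
  bnd <- which(cnt[fk] == 1L)
  bfaces <- cf$faces[bnd, , drop = FALSE]
  xm <- (vertices[bfaces[, 1], 1] + vertices[bfaces[, 2], 1]) / 2
  ym <- (vertices[bfaces[, 1], 2] + vertices[bfaces[, 2], 2]) / 2
  tol <- 1e-9 * max(Lx, Ly)
  tags <- ifelse(abs(xm) < tol, 2L,
          ifelse(abs(xm - Lx) < tol, 3L,
          ifelse(abs(ym) < tol, 4L, 5L)))
  parent_mesh(vertices, cells,
              cell_tags = rep(1L, nrow(cells)),
              facets = bfaces, facet_tags = tags,
              cell_tag_names = list(`1` = "domain"),
              facet_tag_names = list(`2` = "left", `3` = "right",
                                     `4` = "bottom", `5` = "top"))
}

# icosahedron subdivided s times, vertices on the unit sphere
.icosphere <- function(subdiv) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    vlist <- list(v)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_mid[[key]]
      if (!is.null(id)) return(id)
      p <- (vlist[[1]][a, ] + vlist[[1]][b, ]) / 2
      p <- p / sqrt(sum(p^2))
      vlist[[1]] <<- rbind(vlist[[1]], p)
      id <- nrow(vlist[[1]])
      edge_mid[[key]] <- id
      id
    }
    r <- 0L
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[r + 1L, ] <- c(a, ab, ca)
      newf[r + 2L, ] <- c(b, bc, ab)
      newf[r + 3L, ] <- c(c, ca, bc)
      newf[r + 4L, ] <- c(ab, bc, ca)
      r <- r + 4L
    }
    v <- vlist[[1]]
    f <- newf
  }
  list(vertices = v, faces = f)
}

# regular polygon ring directions in 2D
.circle_dirs <- function(nseg) {
  th <- 2 * pi * (seq_len(nseg) - 1L) / nseg
  cbind(cos(th), sin(th))
}

# split the prism between two radial layers of one surface triangle into
# tetrahedra, using the global min-vertex-index rule on each quad face so
# the triangulation conforms between neighbouring prisms
.prism_to_tets <- function(bot, top) {
  # bot = c(a,b,c), top = c(d,e,f) global indices, a-d, b-e, c-f aligned
  a <- bot[1]; b <- bot[2]; c <- bot[3]
  d <- top[1]; e <- top[2]; f <- top[3]
  # quad faces: (a,b,e,d), (b,c,f,e), (c,a,d,f); diagonal from min vertex
  diag1 <- min(a, e) < min(b, d)  # TRUE: diagonal a-e, else b-d
  diag2 <- min(b, f) < min(c, e)  # TRUE: b-f else c-e
  diag3 <- min(c, d) < min(a, f)  # TRUE: c-d else a-f
  key <- paste0(as.integer(diag1), as.integer(diag2), as.integer(diag3))
  tets <- switch(key,
    "110" = rbind(c(a, b, e, f), c(a, e, f, d), c(a, b, c, f)),
    "011" = rbind(c(b, c, f, d), c(b, d, e, f), c(a, b, c, d)),
    "101" = rbind(c(a, c, d, e), c(c, d, e, f), c(a, b, c, e)),
    "100" = rbind(c(a, b, c, e), c(a, c, e, f), c(a, e, f, d)),
    "010" = rbind(c(a, b, c, f), c(a, b, d, f), c(b, d, e, f)),
    "001" = rbind(c(a, b, c, d), c(b, c, d, e), c(c, d, e, f)),
    NULL)
  if (is.null(tets)) {
    # "000"/"111" are the cyclic-diagonal cases; the min-vertex rule cannot
    # produce them (they would require a 3-cycle of strict minima)
    stop("internal error: inconsistent prism diagonals", call. = FALSE)
  }
  tets
}

#' Nested spheres or disks (cell with one organelle)
#'
#' Generates a ball of radius `outer_radius` containing a concentric ball of
#' radius `inner_radius`, meshed radially from a subdivided icosahedron
#' (3D) or a regular polygon (2D).  Two volume tags: 1 "cytosol" (shell) and
#' 2 "organelle" (core); two surface tags: 3 "PM" (exterior) and 4
#' "organelle_membrane" (interior interface).
#'
#' @param outer_radius,inner_radius radii in micrometres,
#'   `0 < inner < outer`.
#' @param h target edge length (micrometres); controls angular and radial
#'   resolution.
#' @param dim 2 or 3.
#' @return a `parent_mesh`.
#' @export
generate_nested <- function(outer_radius, inner_radius, h, dim = 3L) {
  if (!(inner_radius > 0 && outer_radius > inner_radius)) {
    stop("require 0 < inner_radius < outer_radius", call. = FALSE)
  }
  if (!(h > 0)) stop("h must be positive", call. = FALSE)
  dim <- as.integer(dim)
  if (!dim %in% c(2L, 3L)) stop("dim must be 2 or 3", call. = FALSE)

  # radial layers: hit inner_radius exactly, step ~ h
  n_in <- max(1L, round(inner_radius / h))
  n_out <- max(1L, round((outer_radius - inner_radius) / h))
  radii <- c(inner_radius * seq_len(n_in) / n_in,
             inner_radius + (outer_radius - inner_radius) * seq_len(n_out) / n_out)
  n_layers <- length(radii)
  inner_layer <- n_in

  if (dim == 3L) {
    subdiv <- max(1L, ceiling(log2(max(1.06 * outer_radius / h, 1))))
    if (subdiv > 5L) {
      stop("geometry error: requested h too small for the radial generator; use a larger h",
           call. = FALSE)
    }
    sph <- .icosphere(subdiv)
    ns <- nrow(sph$vertices)
    vertices <- rbind(c(0, 0, 0),
                      do.call(rbind, lapply(radii, function(r) sph$vertices * r)))
    lay <- function(k) 1L + (k - 1L) * ns  # offset of layer k (k=1 innermost)
    cells <- list()
    # core fan: center to layer 1
    cells[[1]] <- cbind(1L, lay(1L) + sph$faces[, 1], lay(1L) + sph$faces[, 2],
                        lay(1L) + sph$faces[, 3])
    for (k in seq_len(n_layers - 1L)) {
      bot_off <- lay(k); top_off <- lay(k + 1L)
      tets <- vector("list", nrow(sph$faces))
      for (i in seq_len(nrow(sph$faces))) {
        tri <- sph$faces[i, ]
        tets[[i]] <- .prism_to_tets(bot_off + tri, top_off + tri)
      }
      cells[[k + 1L]] <- do.call(rbind, tets)
    }
    cell_tags <- unlist(lapply(seq_along(cells), function(b) {
      outer_layer <- if (b == 1L) 1L else b  # block b spans layers b-1 .. b
      tag <- if (outer_layer <= inner_layer) 2L else 1L
      rep(tag, nrow(cells[[b]]))
    }))
    cells <- do.call(rbind, cells)
    # surfaces: triangles on the inner interface layer and on the outer hull
    inner_faces <- lay(inner_layer) + sph$faces
    outer_faces <- lay(n_layers) + sph$faces
    facets <- rbind(outer_faces, inner_faces)
    facet_tags <- c(rep(3L, nrow(outer_faces)), rep(4L, nrow(inner_faces)))
  } else {
    nseg <- max(8L, ceiling(2 * pi * outer_radius / h))
    dirs <- .circle_dirs(nseg)
    vertices <- rbind(c(0, 0),
                      do.call(rbind, lapply(radii, function(r) dirs * r)))
    lay <- function(k) 1L + (k - 1L) * nseg  # id = lay(k) + j, j in 1..nseg
    nxt <- c(seq_len(nseg - 1L) + 1L, 1L)
    cells <- list()
    cells[[1]] <- cbind(1L, lay(1L) + seq_len(nseg), lay(1L) + nxt)
    for (k in seq_len(n_layers - 1L)) {
      b0 <- lay(k); t0 <- lay(k + 1L)
      i1 <- b0 + seq_len(nseg); i2 <- b0 + nxt
      j1 <- t0 + seq_len(nseg); j2 <- t0 + nxt
      cells[[k + 1L]] <- rbind(cbind(i1, i2, j2), cbind(i1, j2, j1))
    }
    cell_tags <- unlist(lapply(seq_along(cells), function(b) {
      outer_layer <- if (b == 1L) 1L else b
      rep(if (outer_layer <= inner_layer) 2L else 1L, nrow(cells[[b]]))
    }))
    cells <- do.call(rbind, cells)
    b0 <- lay(inner_layer)
    inner_edges <- cbind(b0 + seq_len(nseg), b0 + nxt)
    t0 <- lay(n_layers)
    outer_edges <- cbind(t0 + seq_len(nseg), t0 + nxt)
    facets <- rbind(outer_edges, inner_edges)
    facet_tags <- c(rep(3L, nseg), rep(4L, nseg))
  }
  parent_mesh(vertices, cells, cell_tags, facets, facet_tags,
              cell_tag_names = list(`1` = "cytosol", `2` = "organelle"),
              facet_tag_names = list(`3` = "PM", `4` = "organelle_membrane"))
}
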