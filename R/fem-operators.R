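# P1 finite-element operators on submesh views.
#
# Exact closed-form integration for constant-coefficient mass and stiffness;
# linearly varying coefficients (the axisymmetric weight r, spatially
# varying D) are integrated exactly for linear variation (closed-form
# moments for mass, centroid value for stiffness, whose integrand has
# element-constant gradients).  Surface stiffness uses the per-triangle
# tangent-plane (cotangent) form, i.e. the discrete Laplace-Beltrami
# operator.  Nonlinear reaction terms elsewhere use vertex (mass-lumped)
# quadrature; the lumped weights are the row sums of these mass matrices.

.sub_vertex_values <- function(sub, f) {
  # evaluate a spatial function (of a coordinate matrix) or recycle a scalar
  if (is.function(f)) {
    v <- f(submesh_coords(sub))
    if (length(v) == 1L) v <- rep(v, sub$n_vertices)
    v
  } else {
    rep(f, length.out = sub$n_vertices)
  }
}

#' Consistent P1 mass matrix of a compartment
#'
#' Exact integration of products of linear basis functions over the
#' submesh; with `weight`, the weight is interpolated linearly from its
#' vertex values and the triple products are integrated in closed form
#' (exact when the weight is linear, e.g. the axisymmetric radius).
#'
#' @param sub a `submesh_view` (volume or surface).
#' @param weight optional spatial weight: scalar, vertex-value vector, or
#'   function of the coordinate matrix.
#' @return sparse symmetric matrix (dgCMatrix), `n_vertices` square.
#' @export
assemble_mass <- function(sub, weight = NULL) {
  ents <- sub$entities
  m <- ncol(ents)            # vertices per element
  k <- m - 1L                # simplex dimension
  meas <- sub$measures
  n <- sub$n_vertices
  ii <- jj <- xx <- list()
  if (is.null(weight)) {
    base <- 1 / ((k + 1) * (k + 2))
    for (i in seq_len(m)) for (j in seq_len(m)) {
      ii[[length(ii) + 1L]] <- ents[, i]
      jj[[length(jj) + 1L]] <- ents[, j]
      xx[[length(xx) + 1L]] <- meas * base * (1 + (i == j))
    }
  } else {
    w <- .sub_vertex_values(sub, weight)
    # closed-form moments: int lam_i lam_j lam_l over a k-simplex
    f3 <- factorial(k) / factorial(3 + k)
    c_iii <- 6 * f3; c_iij <- 2 * f3; c_ijl <- 1 * f3
    for (i in seq_len(m)) for (j in seq_len(m)) {
      acc <- numeric(nrow(ents))
      for (l in seq_len(m)) {
        cc <- if (i == j && j == l) c_iii
              else if (i == j || j == l || i == l) c_iij
              else c_ijl
        acc <- acc + w[ents[, l]] * cc
      }
      ii[[length(ii) + 1L]] <- ents[, i]
      jj[[length(jj) + 1L]] <- ents[, j]
      xx[[length(xx) + 1L]] <- meas * acc
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

# element-constant barycentric gradients for tetrahedra; returns a list of
# m matrices (one per local vertex), each n_elem x 3
.tet_gradients <- function(coords, ents) {
  p1 <- coords[ents[, 1], , drop = FALSE]
  e1 <- coords[ents[, 2], , drop = FALSE] - p1
  e2 <- coords[ents[, 3], , drop = FALSE] - p1
  e3 <- coords[ents[, 4], , drop = FALSE] - p1
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c23 <- cross(e2, e3); c31 <- cross(e3, e1); c12 <- cross(e1, e2)
  det <- rowSums(e1 * c23)   # 6V, positive by orientation
  g2 <- c23 / det; g3 <- c31 / det; g4 <- c12 / det
  g1 <- -(g2 + g3 + g4)
  list(g1, g2, g3, g4)
}

.tri_gradients_2d <- function(coords, ents) {
  p1 <- coords[ents[, 1], , drop = FALSE]
  e1 <- coords[ents[, 2], , drop = FALSE] - p1
  e2 <- coords[ents[, 3], , drop = FALSE] - p1
  det <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]  # 2A, positive
  g2 <- cbind(e2[, 2], -e2[, 1]) / det
  g3 <- cbind(-e1[, 2], e1[, 1]) / det
  g1 <- -(g2 + g3)
  list(g1, g2, g3)
}

#' P1 stiffness matrix (volume gradient or Laplace-Beltrami)
#'
#' For volume submeshes: `K_ij = int D grad(phi_i) . grad(phi_j)`.  For
#' surface submeshes of a 3D mesh, gradients are taken in each triangle's
#' tangent plane (cotangent form), giving the discrete Laplace-Beltrami
#' operator; 1D surface facets of a 2D mesh use the intrinsic arclength
#' derivative.  `D` may be a scalar, vertex vector or spatial function;
#' spatially varying coefficients are evaluated at element centroids
#' (exact for linear variation since P1 gradients are element-constant).
#' An optional `weight` (axisymmetric radius) multiplies `D` the same way.
#'
#' @param sub a `submesh_view`.
#' @param D diffusivity (um^2 s^-1), non-negative.
#' @param weight optional spatial weight, as in [assemble_mass()].
#' @return sparse symmetric positive semidefinite matrix with constants in
#'   its null space.
#' @export
assemble_stiffness <- function(sub, D, weight = NULL) {
  ents <- sub$entities
  m <- ncol(ents)
  n <- sub$n_vertices
  coords <- submesh_coords(sub)
  Dv <- .sub_vertex_values(sub, D)
  if (any(Dv < 0)) stop("model error: negative diffusivity sampled", call. = FALSE)
  De <- rowMeans(matrix(Dv[ents], nrow = nrow(ents)))  # centroid value
  if (!is.null(weight)) {
    wv <- .sub_vertex_values(sub, weight)
    De <- De * rowMeans(matrix(wv[ents], nrow = nrow(ents)))
  }
  ii <- jj <- xx <- list()
  push <- function(i, j, x) {
    ii[[length(ii) + 1L]] <<- i; jj[[length(jj) + 1L]] <<- j
    xx[[length(xx) + 1L]] <<- x
  }
  if (m == 4L) {
    g <- .tet_gradients(coords, ents)
    for (i in seq_len(4)) for (j in seq_len(4)) {
      push(ents[, i], ents[, j], De * sub$measures * rowSums(g[[i]] * g[[j]]))
    }
  } else if (m == 3L) {
    # cotangent form: valid for planar triangles in 2D and for triangles
    # embedded in 3D (tangent-plane gradients)
    p <- lapply(1:3, function(i) coords[ents[, i], , drop = FALSE])
    cot_at <- function(k) {
      i <- (k %% 3L) + 1L; j <- ((k + 1L) %% 3L) + 1L
      u <- p[[i]] - p[[k]]; v <- p[[j]] - p[[k]]
      dot <- rowSums(u * v)
      if (ncol(coords) == 3L) {
        cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                    u[, 3] * v[, 1] - u[, 1] * v[, 3],
                    u[, 1] * v[, 2] - u[, 2] * v[, 1])
        nrm <- sqrt(rowSums(cr^2))
      } else {
        nrm <- abs(u[, 1] * v[, 2] - u[, 2] * v[, 1])
      }
      dot / nrm
    }
    for (k in 1:3) {
      i <- (k %% 3L) + 1L; j <- ((k + 1L) %% 3L) + 1L
      off <- -De * cot_at(k) / 2
      push(ents[, i], ents[, j], off)
      push(ents[, j], ents[, i], off)
      push(ents[, i], ents[, i], -off)
      push(ents[, j], ents[, j], -off)
    }
  } else if (m == 2L) {
    L <- sub$measures
    v <- De / L
    push(ents[, 1], ents[, 1], v); push(ents[, 2], ents[, 2], v)
    push(ents[, 1], ents[, 2], -v); push(ents[, 2], ents[, 1], -v)
  } else {
    stop("unsupported element type", call. = FALSE)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

#' Lumped quadrature weights of a compartment
#'
#' Row sums of the (optionally weighted) consistent mass matrix: the vertex
#' quadrature weights used for nonlinear reaction terms.
#' @inheritParams assemble_mass
#' @return numeric vector of length `n_vertices`.
#' @export
lumped_mass <- function(sub, weight = NULL) {
  as.numeric(Matrix::rowSums(assemble_mass(sub, weight)))
}

#' Trace operator from a volume compartment onto a bordering surface
#'
#' Boolean vertex-injection matrix `T` with one unit entry per row:
#' `T %*% u` restricts volume nodal values to the surface vertices.
#'
#' @param volume `submesh_view` of the volume compartment.
#' @param surface `submesh_view` of the surface.
#' @return sparse matrix, rows = surface dofs, cols = volume dofs.
#' @export
trace_operator <- function(volume, surface) {
  vol_local <- integer(nrow(volume$mesh$vertices))
  vol_local[volume$vertex_parent] <- seq_along(volume$vertex_parent)
  cols <- vol_local[surface$vertex_parent]
  if (any(cols == 0L)) {
    stop("mesh consistency error: surface vertex absent from the volume submesh",
         call. = FALSE)
  }
  Matrix::sparseMatrix(i = seq_along(cols), j = cols, x = 1,
                       dims = c(length(cols), volume$n_vertices))
}

#' Axisymmetric quadrature weight
#'
#' For a 2D (r, z) half-section, returns the per-vertex weight `w = r`
#' (first coordinate).  All volume and boundary integrals are then weighted
#' by r, so compartment measures report `2 * pi * int r dOmega` (cylindrical
#' volume) when multiplied by `2 * pi`.  Vertices with `r < -tol` are a
#' geometry error; the r = 0 axis carries zero measure naturally.
#'
#' @param mesh a 2D `parent_mesh` in (r, z).
#' @return numeric vector of per-vertex weights over the parent mesh.
#' @export
axisymmetric_weight <- function(mesh) {
  if (mesh$dim != 2L) {
    stop("axisymmetric weighting requires a 2D (r, z) mesh", call. = FALSE)
  }
  r <- mesh$vertices[, 1]
  tol <- 1e-9 * max(abs(mesh$vertices))
  if (any(r < -tol)) {
    stop("geometry error: vertices with negative radial coordinate", call. = FALSE)
  }
  pmax(r, 0)
}

# quadrature points (barycentric) exact for degree-2 integrands
.quad_rule <- function(m) {
  if (m == 4L) {
    a <- 0.585410196624968515; b <- 0.138196601125010515
    list(bary = rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a)),
         w = rep(1 / 4, 4))
  } else if (m == 3L) {
    list(bary = rbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5)),
         w = rep(1 / 3, 3))
  } else {
    g <- 1 / (2 * sqrt(3))
    list(bary = rbind(c(0.5 + g, 0.5 - g), c(0.5 - g, 0.5 + g)),
         w = rep(1 / 2, 2))
  }
}

# integrate f(x) * (optionally) nodal field against quadrature over a
# submesh; returns per-element contributions summed.  `fun` receives the
# physical quadrature coordinates (matrix) and must return a vector.
integrate_submesh <- function(sub, fun, nodal = NULL, weight = NULL) {
  ents <- sub$entities
  m <- ncol(ents)
  coords <- submesh_coords(sub)
  q <- .quad_rule(m)
  total <- 0
  wv <- if (is.null(weight)) NULL else .sub_vertex_values(sub, weight)
  for (k in seq_len(nrow(q$bary))) {
    lam <- q$bary[k, ]
    pts <- matrix(0, nrow(ents), ncol(coords))
    for (i in seq_len(m)) pts <- pts + lam[i] * coords[ents[, i], , drop = FALSE]
    vals <- if (is.null(fun)) 1 else fun(pts)
    if (!is.null(nodal)) {
      uh <- numeric(nrow(ents))
      for (i in seq_len(m)) uh <- uh + lam[i] * nodal[ents[, i]]
      vals <- if (is.null(fun)) uh else vals * uh
    }
    if (!is.null(wv)) {
      wq <- numeric(nrow(ents))
      for (i in seq_len(m)) wq <- wq + lam[i] * wv[ents[, i]]
      vals <- vals * wq
    }
    total <- total + sum(q$w[k] * sub$measures * vals)
  }
  total
}
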