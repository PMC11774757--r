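# Mesh layer: generators, MSH I/O, submeshes, adjacency, invariants.

test_that("unit tetrahedron MSH fixture loads with correct geometry", {
  path <- system.file("extdata", "unit_tet.msh", package = "rdmix")
  m <- load_gmsh(path)
  expect_equal(nrow(m$cells), 1L)
  expect_equal(nrow(m$facets), 4L)
  expect_equal(sum(m$cell_measures), 1 / 6, tolerance = 1e-14)
  expect_equal(sort(unique(m$facet_tags)), 2:5)
})

test_that("MSH 2.2 headers and malformed files are rejected", {
  p <- withr::local_tempfile(fileext = ".msh")
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), p)
  expect_error(load_gmsh(p), "format error.*2\\.2|not supported")
  p2 <- withr::local_tempfile(fileext = ".msh")
  writeLines("not a mesh", p2)
  expect_error(load_gmsh(p2), "format error")
  expect_error(load_gmsh("no/such/file.msh"), "not found")
})

test_that("generated slabs have exact volumes and tagged faces", {
  m1 <- generate_slab(1, 1, 1, 1)
  expect_equal(nrow(m1$cells), 6L)  # Kuhn subdivision of one box
  expect_equal(sum(m1$cell_measures), 1, tolerance = 1e-12)

  m2 <- generate_slab(1, 1, 5, 2)
  expect_equal(sum(m2$cell_measures), 5, tolerance = 5 * 1e-12)
  expect_equal(tag_measure(m2, 2, "facet"), 1, tolerance = 1e-12)
  # all membrane facets lie in z = 0
  mem <- m2$facets[m2$facet_tags == 2L, ]
  expect_true(all(abs(m2$vertices[as.vector(mem), 3]) < 1e-12))

  m4 <- generate_slab(1, 1, 5, 4)
  expect_equal(sum(m4$facet_tags == 2L), 4L * sum(m2$facet_tags == 2L))
  expect_error(generate_slab(-1, 1, 1, 2), "positive")
})

test_that("two-box mesh: interior facets have two cells with opposite normals", {
  m <- make_two_box(2)
  adj <- surface_adjacency(m, 9)
  expect_equal(adj$volumes, c(1L, 2L))
  expect_equal(ncol(adj$cells), 2L)
  expect_true(all(m$cell_tags[adj$cells[, 1]] == 1L))
  expect_true(all(m$cell_tags[adj$cells[, 2]] == 2L))
  expect_equal(adj$normals[[1]] + adj$normals[[2]],
               matrix(0, nrow(adj$normals[[1]]), 3))
  # MSH round trip preserves the two-volume structure
  p <- withr::local_tempfile(fileext = ".msh")
  write_gmsh(m, p)
  m2 <- load_gmsh(p)
  expect_equal(sort(unique(m2$cell_tags)), c(1L, 2L))
  expect_equal(sum(m2$cell_measures), sum(m$cell_measures), tolerance = 1e-12)
})

test_that("nested generators approach exact areas as h shrinks", {
  n2 <- generate_nested(2, 1, 0.4, dim = 2)
  expect_equal(tag_measure(n2, 1, "cell"), 3 * pi, tolerance = 0.03)
  expect_error(generate_nested(1, 2, 0.2), "inner_radius < outer_radius")

  a_coarse <- tag_measure(generate_nested(2, 1, 0.5, dim = 3), 4, "facet")
  a_fine <- tag_measure(generate_nested(2, 1, 0.25, dim = 3), 4, "facet")
  expect_true(a_coarse < a_fine)       # inscribed: monotone from below
  expect_true(a_fine < 4 * pi)
  expect_lt(abs(a_fine - 4 * pi), abs(a_coarse - 4 * pi))
  expect_lt(abs(a_fine - 4 * pi) / (4 * pi), 0.01)
})

test_that("submesh extraction satisfies the round-trip and subset properties", {
  m <- generate_slab(1, 1, 1, 2)
  sv <- extract_submesh(m, 1, "cell")
  expect_equal(nrow(sv$entities), nrow(m$cells))
  expect_equal(sv$n_vertices, nrow(m$vertices))
  # round trip local -> parent -> local
  expect_equal(sv$vertex_parent[sv$entities[1, ]], m$cells[sv$entity_parent[1], ])

  sm <- extract_submesh(m, "membrane", "facet")
  expect_true(all(abs(m$vertices[sm$vertex_parent, 3]) < 1e-12))
  expect_error(extract_submesh(m, 99, "facet"), "available tags")

  n3 <- generate_nested(2, 1, 0.5, dim = 3)
  om <- extract_submesh(n3, 4, "facet")
  s1 <- extract_submesh(n3, 1, "cell")
  s2 <- extract_submesh(n3, 2, "cell")
  expect_true(all(om$vertex_parent %in% s1$vertex_parent))
  expect_true(all(om$vertex_parent %in% s2$vertex_parent))
})

test_that("surface adjacency resolves sides and normals", {
  m <- generate_slab(1, 1, 1, 2)
  adj <- surface_adjacency(m, "membrane")
  expect_equal(adj$volumes, 1L)
  expect_equal(unique(adj$normals[[1]]), matrix(c(0, 0, -1), 1))

  n3 <- generate_nested(2, 1, 0.5, dim = 3)
  pm <- surface_adjacency(n3, "PM")
  expect_equal(pm$volumes, 1L)  # exterior borders the shell only
})

test_that("tag partition and refinement invariants hold", {
  m <- make_two_box(2)
  expect_equal(tag_measure(m, 1, "cell") + tag_measure(m, 2, "cell"),
               sum(m$cell_measures), tolerance = 1e-12)
  # refinement: more cells, boundary-measure error does not increase
  for (dim in 2:3) {
    mc <- generate_nested(2, 1, 0.6, dim = dim)
    mf <- generate_nested(2, 1, 0.3, dim = dim)
    expect_gt(nrow(mf$cells), nrow(mc$cells))
    exact <- if (dim == 2) 2 * pi * 2 else 4 * pi * 4
    expect_lte(abs(tag_measure(mf, 3, "facet") - exact),
               abs(tag_measure(mc, 3, "facet") - exact))
  }
})

test_that("degenerate and mistagged meshes are rejected", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))  # coplanar
  expect_error(parent_mesh(v, matrix(1:4, 1), 1L,
                           matrix(c(1, 2, 3), 1), 2L),
               "degenerate cell")
  # interior membrane between like-tagged cells must be declared
  m <- generate_slab(1, 1, 2, 2)
  two <- make_two_box(2)
  expect_error(parent_mesh(two$vertices, two$cells,
                           rep(1L, nrow(two$cells)),
                           two$facets, two$facet_tags),
               "internal_membranes")
  ok <- parent_mesh(two$vertices, two$cells, rep(1L, nrow(two$cells)),
                    two$facets, two$facet_tags, internal_membranes = 9L)
  expect_s3_class(ok, "parent_mesh")
})
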