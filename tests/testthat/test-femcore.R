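# P1 operators: mass, stiffness, traces, reaction assembly, axisymmetry.

unit_tet_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  parent_mesh(v, matrix(1:4, 1), 1L,
              rbind(c(1, 2, 3), c(2, 3, 4)), c(2L, 3L))
}

test_that("mass matrices match exact simplex integrals", {
  m <- unit_tet_mesh()
  sub <- extract_submesh(m, 1, "cell")
  M <- as.matrix(assemble_mass(sub))
  expect_equal(diag(M), rep(1 / 60, 4), tolerance = 1e-15)
  expect_equal(M[1, 2], 1 / 120, tolerance = 1e-15)
  expect_equal(sum(M), 1 / 6, tolerance = 1e-15)  # partition of unity

  # surface triangle (oblique face, area A): diag A/6, off-diag A/12
  st <- extract_submesh(m, 3, "facet")
  A <- sum(st$measures)
  Ms <- as.matrix(assemble_mass(st))
  expect_equal(diag(Ms), rep(A / 6, 3), tolerance = 1e-15)
  expect_equal(Ms[1, 2], A / 12, tolerance = 1e-15)

  # any mesh: entrywise sum equals the submesh measure
  n3 <- generate_nested(2, 1, 0.5, dim = 3)
  for (tg in list(c(1, "cell"), c(4, "facet"))) {
    s <- extract_submesh(n3, as.integer(tg[1]), tg[2])
    expect_equal(sum(assemble_mass(s)), sum(s$measures), tolerance = 1e-12)
  }
})

test_that("stiffness matrices annihilate constants and reproduce Dirichlet energies", {
  n3 <- generate_nested(2, 1, 0.5, dim = 3)
  sub <- extract_submesh(n3, 1, "cell")
  K <- assemble_stiffness(sub, 1.0)
  ones <- rep(1, sub$n_vertices)
  expect_lt(max(abs(K %*% ones)), 1e-12 * max(abs(K)))

  # unit square, u = x interpolant: u' K u = D
  r <- generate_rect(1, 1, 4, 4)
  sr <- extract_submesh(r, 1, "cell")
  K2 <- assemble_stiffness(sr, 3.0)
  u <- rdmix:::submesh_coords(sr)[, 1]
  expect_equal(as.numeric(t(u) %*% K2 %*% u), 3.0, tolerance = 1e-12)

  # Laplace-Beltrami on the unit sphere: energy of z -> D * 8 pi / 3
  target <- 8 * pi / 3
  errs <- vapply(c(0.5, 0.25), function(h) {
    s3 <- generate_nested(1, 0.5, h, dim = 3)
    ss <- extract_submesh(s3, 3, "facet")
    KS <- assemble_stiffness(ss, 1.0)
    uz <- rdmix:::submesh_coords(ss)[, 3]
    abs(as.numeric(t(uz) %*% KS %*% uz) - target)
  }, 1)
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2] / target, 0.01)

  expect_error(assemble_stiffness(sub, -1), "negative diffusivity")
})

test_that("trace operators are boolean injections consistent with boundary integrals", {
  m <- generate_slab(1, 1, 1, 2)
  vol <- extract_submesh(m, 1, "cell")
  srf <- extract_submesh(m, 2, "facet")
  Tr <- trace_operator(vol, srf)
  expect_true(all(Matrix::rowSums(Tr) == 1))
  expect_equal(as.numeric(Tr %*% rep(1, vol$n_vertices)),
               rep(1, srf$n_vertices))

  # traces from both sides of an interior interface agree for a globally
  # continuous function
  n3 <- generate_nested(2, 1, 0.5, dim = 3)
  om <- extract_submesh(n3, 4, "facet")
  s1 <- extract_submesh(n3, 1, "cell")
  s2 <- extract_submesh(n3, 2, "cell")
  f <- function(p) p[, 1] + 2 * p[, 2] - p[, 3]
  t1 <- as.numeric(trace_operator(s1, om) %*% f(rdmix:::submesh_coords(s1)))
  t2 <- as.numeric(trace_operator(s2, om) %*% f(rdmix:::submesh_coords(s2)))
  expect_equal(t1, t2)

  # T' Ms T reproduces the boundary integral of a linear function:
  # int_{z=0} x dA = 1/2 on the unit slab membrane
  Ms <- assemble_mass(srf)
  x <- rdmix:::submesh_coords(vol)[, 1]
  ones_s <- rep(1, srf$n_vertices)
  val <- as.numeric(t(ones_s) %*% Ms %*% (Tr %*% x))
  expect_equal(val, 0.5, tolerance = 1e-13)
})

test_that("reaction assembly is consistent, antisymmetric and exactly differentiated", {
  # zero-rate model: zero residual contribution and Jacobian
  cfg <- list(
    compartments = list(list(name = "v", kind = "volume", tag = 1),
                        list(name = "mem", kind = "surface", tag = 2,
                             borders = list("v"))),
    species = list(list(name = "X", compartment = "v", D = 1, initial = 1)),
    parameters = list(list(name = "k0", value = 0)),
    reactions = list(list(name = "nil", type = "volume", compartment = "v",
                          rate = "k0*X", stoich = list(X = 1))))
  m0 <- validate_model(build_containers(cfg), generate_slab(1, 1, 1, 2))
  sys0 <- rdmix:::build_system(m0)
  r0 <- rdmix:::assemble_reaction(sys0, rdmix:::model_initial_state(m0), 0,
                                  list(k0 = 0))
  expect_equal(max(abs(r0$load)), 0)
  expect_equal(max(abs(unlist(r0$jac$x))), 0)

  # volume-surface-volume transport: equal and opposite volume loads
  nm <- nested_transport_model(dim = 2, h = 0.4)
  sys <- rdmix:::build_system(nm)
  u <- rdmix:::model_initial_state(nm)
  r <- rdmix:::assemble_reaction(sys, u, 0, list(kperm = 1))
  dofl <- sys$dof
  la <- r$load[rdmix:::species_slice(dofl, "Ca_cyto")]
  lb <- r$load[rdmix:::species_slice(dofl, "Ca_org")]
  expect_equal(sum(la), -sum(lb), tolerance = 1e-12)

  # symbolic Jacobian vs central finite differences on a nonlinear variant
  cfg2 <- nm$containers
  cfg2$reactions$om_transport$rate <-
    "kperm*(Ca_cyto*Ca_cyto/(0.5 + Ca_cyto) - Ca_org)"
  nm2 <- validate_model(cfg2, nm$mesh)
  expect_lt(fd_jacobian_error(nm2, seed = 3), 1e-6)
})

test_that("axisymmetric weighting reproduces cylindrical measures and 3D physics", {
  # rectangle [0,R] x [0,H]: weighted measure R^2 H / 2
  R <- 2; H <- 3
  rx <- generate_rect(R, H, 4, 4)
  w <- axisymmetric_weight(rx)
  sub <- extract_submesh(rx, 1, "cell")
  Mw <- assemble_mass(sub, w[sub$vertex_parent])
  expect_equal(sum(Mw), R^2 * H / 2, tolerance = 1e-12)
  expect_equal(sum(lumped_mass(sub, w[sub$vertex_parent])), R^2 * H / 2,
               tolerance = 1e-12)

  # an (r,z) half-section with z-only dynamics must match the 3D slab:
  # membrane flux at z = 0, decay in the volume (a cylinder of radius R
  # with no-flux sides is exactly the slab problem along z)
  p <- slab_problem(D = 10)
  mesh2 <- generate_rect(1, 1, 6, 6)
  cfg <- list(
    compartments = list(
      list(name = "cytosol", kind = "volume", tag = 1),
      list(name = "membrane", kind = "surface", tag = 4,
           borders = list("cytosol"))),
    species = list(
      list(name = "A", compartment = "cytosol", D = p$D, initial = p$A_tot),
      list(name = "Ap", compartment = "cytosol", D = p$D, initial = 0)),
    parameters = list(list(name = "kkin", value = p$k_kin, unit = "um/s"),
                      list(name = "kp", value = p$k_p, unit = "1/s")),
    reactions = list(
      list(name = "phos", type = "volume_surface", compartment = "membrane",
           rate = "kkin*A", stoich = list(A = -1, Ap = 1),
           rate_unit = "uM*um/s"),
      list(name = "dephos", type = "volume", compartment = "cytosol",
           rate = "kp*Ap", stoich = list(A = 1, Ap = -1))))
  maxi <- validate_model(build_containers(cfg), mesh2, axisymmetric = TRUE)
  s <- run_simulation(maxi, t_final = 1e4, dt = 5, steady_tol = 1e-10)
  exact <- analytic_slab(p)
  sub2 <- maxi$submeshes$cytosol
  err <- l2_error(sub2, s$fields[[length(s$times)]]$Ap,
                  function(pt) exact$Ap(pt[, 2]),
                  weight = maxi$weight[sub2$vertex_parent])
  # normalize by the weighted domain measure
  expect_lt(err / sqrt(1 / 2), 2e-4)
  expect_error(axisymmetric_weight(generate_slab(1, 1, 1, 1)), "2D")
})
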