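# Verification machinery: analytic solution, L2 errors, convergence orders,
# ODE limit.

test_that("the analytic slab profile satisfies its ODE and boundary conditions", {
  p <- slab_problem(D = 10, k_kin = 1.5, k_p = 2, A_tot = 1.2)
  ex <- analytic_slab(p)
  # no phosphorylation: identically zero
  ex0 <- analytic_slab(slab_problem(D = 10, k_kin = 0))
  expect_equal(ex0$Ap(seq(0, 1, 0.1)), rep(0, 11))

  # interior residual D u'' - kp u = 0 via high-order finite differences
  z <- seq(0.1, p$L - 0.1, length.out = 7)
  h <- 1e-4
  upp <- (ex$Ap(z + h) - 2 * ex$Ap(z) + ex$Ap(z - h)) / h^2
  expect_equal(p$D * upp, p$k_p * ex$Ap(z), tolerance = 1e-6)
  # membrane flux balance: -D u'(0) = kkin (Atot - u(0))
  up0 <- (ex$Ap(h) - ex$Ap(-h)) / (2 * h)
  expect_equal(-p$D * up0, p$k_kin * (p$A_tot - ex$Ap(0)), tolerance = 1e-6)
  # no-flux at z = L
  upL <- (ex$Ap(p$L + h) - ex$Ap(p$L - h)) / (2 * h)
  expect_equal(p$D * upL, 0, tolerance = 1e-8)

  # flux balance integrated: kp * int Ap = kkin * A(0)
  int_Ap <- ex$C * ex$lambda * sinh(p$L / ex$lambda)
  expect_equal(p$k_p * int_Ap, p$k_kin * ex$A(0), tolerance = 1e-12)
})

test_that("the closed form matches an independent 1D boundary-value solve", {
  p <- slab_problem(D = 10)
  ex <- analytic_slab(p)
  bvp <- slab_bvp_oracle(p, N = 20000)
  expect_equal(bvp$u, ex$Ap(bvp$z), tolerance = 1e-8)
})

test_that("the L2 error functional is exact, scaling and translation invariant", {
  m <- generate_slab(1, 1, 1, 4)
  sub <- extract_submesh(m, 1, "cell")
  coords <- rdmix:::submesh_coords(sub)
  lin <- 1 + 2 * coords[, 1] - coords[, 3]
  expect_lt(l2_error(sub, lin, function(p) 1 + 2 * p[, 1] - p[, 3]), 1e-13)

  # z^2 interpolation error: each tet spans one z-layer, so the closed
  # form reduces to the 1D result, ||e||^2 = n * (1/n)^5 / 30
  for (n in c(2, 4)) {
    mn <- generate_slab(1, 1, 1, n)
    sn <- extract_submesh(mn, 1, "cell")
    zz <- rdmix:::submesh_coords(sn)[, 3]^2
    got <- l2_error(sn, zz, function(p) p[, 3]^2)
    expect_equal(got, sqrt(1 / (30 * n^4)), tolerance = 0.05)
  }

  # rigid translation leaves the error unchanged
  shift <- c(0.3, -1.2, 5)
  mt <- parent_mesh(sweep(m$vertices, 2, shift, "+"), m$cells, m$cell_tags,
                    m$facets, m$facet_tags)
  st <- extract_submesh(mt, 1, "cell")
  z2 <- (rdmix:::submesh_coords(st)[, 3] - shift[3])^2
  expect_equal(l2_error(st, z2, function(p) (p[, 3] - shift[3])^2),
               l2_error(sub, coords[, 3]^2, function(p) p[, 3]^2),
               tolerance = 1e-12)
})

test_that("the slab steady state converges at second order in h", {
  r <- convergence_study(slab_problem(D = 10), "h", levels = 3)
  expect_gt(r$fitted_order, 1.6)
  expect_lt(r$fitted_order, 2.3)
  expect_true(all(diff(r$table$error) < 0))
  # finest-level solution also matches the independent BVP oracle scale
  expect_lt(r$table$error[3], 1e-4)
})

test_that("the ODE limit check behaves as a well-mixed diagnostic", {
  # no reactions: deviation at solver tolerance
  cfg <- list(
    compartments = list(list(name = "v", kind = "volume", tag = 1),
                        list(name = "mem", kind = "surface", tag = 2,
                             borders = list("v"))),
    species = list(list(name = "X", compartment = "v", D = 1, initial = 1)))
  m0 <- validate_model(build_containers(cfg), generate_slab(1, 1, 1, 2))
  chk0 <- ode_limit_check(m0, D_large = 100, t_final = 0.5, dt = 0.05)
  expect_lt(chk0$deviation, 1e-10)

  # binding fixture: deviation shrinks from D = 10 to D = 1000
  m <- binding_model(n = 2)
  d10 <- ode_limit_check(m, D_large = 10, t_final = 1, dt = 0.005)$deviation
  d1000 <- ode_limit_check(m, D_large = 1000, t_final = 1, dt = 0.005)$deviation
  expect_gt(d10, d1000)
  expect_lt(d1000, 0.01)
})
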