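# Model layer: containers, rate parsing, validation, reductions, units.

test_that("containers build from minimal and fixture configs", {
  cfg <- list(
    compartments = list(list(name = "v", kind = "volume", tag = 1)),
    species = list(list(name = "X", compartment = "v", D = 1)))
  cont <- build_containers(cfg)
  expect_s3_class(cont, "rd_containers")
  expect_named(cont$species, "X")

  bad <- cfg
  bad$species[[1]]$frobnicate <- 2
  expect_error(build_containers(bad), "unknown key 'frobnicate'")
  bad2 <- cfg
  bad2$species[[1]]$D <- NULL
  expect_error(build_containers(bad2), "missing required field 'D'")
  dup <- cfg
  dup$species <- c(cfg$species, cfg$species)
  expect_error(build_containers(dup), "duplicate name")
})

test_that("the shipped slab config has the expected structure", {
  cfg <- read_model_config(system.file("extdata", "slab_phosphorylation.yml",
                                       package = "rdmix"))
  cont <- build_containers(cfg)
  kinds <- vapply(cont$compartments, `[[`, "", "kind")
  expect_equal(sum(kinds == "volume"), 1L)
  expect_equal(sum(kinds == "surface"), 1L)
  expect_length(cont$species, 2L)
  types <- vapply(cont$reactions, `[[`, "", "type")
  expect_equal(sum(types == "volume"), 1L)
  expect_equal(sum(types == "volume_surface"), 1L)
  # round trip: write + reread gives identical containers
  p <- withr::local_tempfile(fileext = ".yml")
  write_model_config(cont, p)
  cont2 <- build_containers(read_model_config(p))
  expect_equal(cont2$species, cont$species)
  expect_equal(cont2$reactions, cont$reactions)
})

test_that("rate parsing produces exact symbolic derivatives", {
  r <- parse_rate("kf*A*B", species = c("A", "B"), parameters = "kf")
  env <- list(kf = 2, A = 3, B = 5)
  expect_equal(eval(r$deriv$A, env), 2 * 5)
  expect_equal(eval(r$deriv$B, env), 2 * 3)

  r2 <- parse_rate("Vmax*C/(Km + C)", species = "C",
                   parameters = c("Vmax", "Km"))
  env2 <- list(Vmax = 7, Km = 0.5, C = 1.3)
  expect_equal(eval(r2$deriv$C, env2), 7 * 0.5 / (0.5 + 1.3)^2,
               tolerance = 1e-14)

  # randomized finite-difference oracle, including the smooth macros
  set.seed(11)
  exprs <- c("kf*A*exp(-B)", "hill(A, Km, 2)*B", "tanh(A - B)",
             "softmin(A, B, 4)")
  for (tx in exprs) {
    rr <- parse_rate(tx, species = c("A", "B"), parameters = c("kf", "Km"))
    for (rep in 1:3) {
      env <- list(kf = runif(1, 0.5, 2), Km = runif(1, 0.5, 2),
                  A = runif(1, 0.2, 2), B = runif(1, 0.2, 2))
      for (sp in rr$species_used) {
        h <- 1e-6 * max(abs(env[[sp]]), 1)
        ep <- env; ep[[sp]] <- env[[sp]] + h
        em <- env; em[[sp]] <- env[[sp]] - h
        fd <- (eval(rr$expr, ep) - eval(rr$expr, em)) / (2 * h)
        expect_equal(eval(rr$deriv[[sp]], env), fd, tolerance = 1e-6)
      }
    }
  }
})

test_that("rate parsing rejects unknown symbols and non-smooth constructs", {
  expect_error(parse_rate("kf*Q", species = "A", parameters = "kf"),
               "unknown symbol 'Q'")
  expect_error(parse_rate("foo(A)", species = "A"), "unknown function 'foo'")
  expect_error(parse_rate("ifelse(A > 1, 1, 0)", species = "A"),
               "event")
})

test_that("validation enforces adjacency, membership and units", {
  m <- slab_model(slab_problem(), 2)
  expect_s3_class(m, "rd_model")

  # volume-surface-volume on an exterior surface (1 bordering volume)
  cfg <- m$containers
  cfg$reactions$phosphorylation$type <- "volume_surface_volume"
  expect_error(validate_model(cfg, m$mesh), "adjacency arity")

  # rate unit not convertible to the canonical volume rate
  cfg2 <- m$containers
  cfg2$reactions$dephosphorylation$rate_unit <- "uM*uM/s"
  expect_error(validate_model(cfg2, m$mesh), "unit")

  # undeclared species symbol in a rate
  cfg3 <- m$containers
  cfg3$reactions$dephosphorylation$rate <- "kp*Zz"
  expect_error(validate_model(cfg3, m$mesh), "unknown symbol 'Zz'")

  # compartment tag absent from the mesh
  cfg4 <- m$containers
  cfg4$compartments$cytosol$tag <- 42L
  expect_error(validate_model(cfg4, m$mesh), "tag")
})

test_that("conservation elimination follows the null space and eligibility rules", {
  m <- ab_model()
  mr <- reduce_by_conservation(m)
  expect_length(mr$reduction, 1L)
  expect_length(mr$species, 1L)

  # different diffusivities: no elimination
  cfg <- m$containers
  cfg$species$B$D <- 0.5
  m2 <- validate_model(cfg, m$mesh)
  expect_null(reduce_by_conservation(m2)$reduction)

  # boundary-flux-touched species are ineligible
  expect_null(reduce_by_conservation(slab_model(slab_problem(), 2))$reduction)

  # random closed network: eliminated count = n - rank(S) (null-space oracle)
  set.seed(42)
  nsp <- 5
  S <- matrix(sample(-2:2, nsp * 3, replace = TRUE), nsp, 3)
  cfg5 <- list(
    compartments = list(list(name = "v", kind = "volume", tag = 1),
                        list(name = "mem", kind = "surface", tag = 2,
                             borders = list("v"))),
    species = lapply(1:nsp, function(i) {
      list(name = paste0("X", i), compartment = "v", D = 1, initial = 1)
    }),
    parameters = list(list(name = "k", value = 0.1)),
    reactions = lapply(1:3, function(j) {
      st <- as.list(S[, j]); names(st) <- paste0("X", 1:nsp)
      list(name = paste0("r", j), type = "volume", compartment = "v",
           rate = "k*X1", stoich = st[S[, j] != 0])
    }))
  mm <- validate_model(build_containers(cfg5), generate_slab(1, 1, 1, 1))
  mred <- reduce_by_conservation(mm)
  expect_length(mred$reduction, nsp - qr(S)$rank)
})

test_that("the well-mixed reduction matches closed forms", {
  # diffusion-only: all derivatives vanish
  cfg <- list(
    compartments = list(list(name = "v", kind = "volume", tag = 1),
                        list(name = "mem", kind = "surface", tag = 2,
                             borders = list("v"))),
    species = list(list(name = "X", compartment = "v", D = 5, initial = 2)))
  m0 <- validate_model(build_containers(cfg), generate_slab(1, 1, 1, 1))
  ode0 <- reduce_to_ode(m0)
  expect_equal(unname(ode0$rhs(0, ode0$y0)), 0)

  # slab fixture: 2-state ODE steady state = spatial average of the
  # analytic profile in the D -> infinity limit (closed form)
  p <- slab_problem(D = 10)
  mslab <- slab_model(p, 2)
  ode <- reduce_to_ode(mslab)
  # steady state: kp*Ap = kkin*(Atot - Ap)*(S/V); S = V = 1 here
  Ap_star <- p$k_kin * p$A_tot / (p$k_p * 1 + p$k_kin)
  y <- c(A = p$A_tot - Ap_star, Ap = Ap_star)
  expect_equal(unname(ode$rhs(0, y)), c(0, 0), tolerance = 1e-12)

  # conservation: the A <-> B reduction preserves A + B exactly
  odeab <- reduce_to_ode(ab_model())
  d <- odeab$rhs(0, c(A = 0.3, B = 0.7))
  expect_equal(unname(d[["A"]] + d[["B"]]), 0, tolerance = 1e-15)

  # space-expression parameters are rejected
  cfgs <- mslab$containers
  cfgs$parameters$kspace <- parameter("kspace", "1 + x", kind = "space")
  msp <- validate_model(cfgs, mslab$mesh)
  expect_error(reduce_to_ode(msp), "well-mixed")
})

test_that("model building is deterministic", {
  m1 <- slab_model(slab_problem(), 2)
  m2 <- slab_model(slab_problem(), 2)
  expect_identical(names(m1$species), names(m2$species))
  expect_identical(rdmix:::model_dofmap(m1), rdmix:::model_dofmap(m2))
  expect_identical(lapply(m1$reactions, function(r) r$rate$text),
                   lapply(m2$reactions, function(r) r$rate$text))
})
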