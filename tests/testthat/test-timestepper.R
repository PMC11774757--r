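# Implicit Euler / Newton stepping: convergence behaviour, step control,
# events, scalar coupling, restart mediation.

logistic_model <- function(kg = 2, X0 = 0.1, n = 1) {
  cfg <- list(
    compartments = list(list(name = "v", kind = "volume", tag = 1),
                        list(name = "mem", kind = "surface", tag = 2,
                             borders = list("v"))),
    species = list(list(name = "X", compartment = "v", D = 1, initial = X0)),
    parameters = list(list(name = "kg", value = kg)),
    reactions = list(list(name = "grow", type = "volume", compartment = "v",
                          rate = "kg*X*(1 - X)", stoich = list(X = 1))))
  validate_model(build_containers(cfg), generate_slab(1, 1, 1, n))
}

test_that("linear systems converge in exactly one Newton iteration", {
  m <- slab_model(slab_problem(), 2)
  s <- run_simulation(m, t_final = 0.5, dt = 0.1)
  expect_equal(unique(s$log$iterations), 1L)
  # from a different (still finite) guess too
  sys <- rdmix:::build_system(m)
  u0 <- rdmix:::model_initial_state(m)
  ps <- list(kkin = 1, kp = 1)
  sol <- newton_solve(sys, u0 + 5, u0, 0.1, 0.1, ps)
  expect_equal(sol$iterations, 1L)
  sol2 <- newton_solve(sys, u0 - 3, u0, 0.1, 0.1, ps)
  expect_lt(max(abs(sol$u - sol2$u)), 1e-8)
})

test_that("a uniform logistic step matches the scalar implicit-Euler root", {
  m <- logistic_model(kg = 2, X0 = 0.1)
  tau <- 0.2
  s <- run_simulation(m, t_final = tau, dt = tau)
  got <- compartment_average(s, "X")
  # independent scalar oracle: u - u0 - tau * kg * u * (1 - u) = 0
  oracle <- uniroot(function(u) u - 0.1 - tau * 2 * u * (1 - u),
                    c(0, 1), tol = 1e-14)$root
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("an unsolvable step raises a step-failure error", {
  # u = u0 - tau*kg*(1 + u^2) has no real root for large tau*kg
  cfg <- list(
    compartments = list(list(name = "v", kind = "volume", tag = 1),
                        list(name = "mem", kind = "surface", tag = 2,
                             borders = list("v"))),
    species = list(list(name = "X", compartment = "v", D = 1, initial = 0.1)),
    parameters = list(list(name = "kg", value = 10)),
    reactions = list(list(name = "sink", type = "volume", compartment = "v",
                          rate = "kg*(1 + X*X)", stoich = list(X = -1))))
  m <- validate_model(build_containers(cfg), generate_slab(1, 1, 1, 1))
  expect_error(
    run_simulation(m, t_final = 1, dt = 1,
                   settings = solver_settings(max_restarts = 0L)),
    "step-failure")
})

test_that("time-step adaptation follows the declared monotone policy", {
  s <- solver_settings(dt_min = 1e-3, dt_max = 1)
  expect_equal(adapt_dt(2, 0.1, s), 0.125)          # grow x1.25
  expect_equal(adapt_dt(3, 0.9, s), 1)              # capped
  expect_equal(adapt_dt(5, 0.1, s), 0.1)            # hold
  expect_equal(adapt_dt(9, 0.1, s), 0.07)           # shrink x0.7
  expect_equal(adapt_dt(25, 0.0012, s), 1e-3)       # floored
  taus <- vapply(1:15, adapt_dt, 1, tau = 0.1, settings = s)
  expect_true(all(diff(taus) <= 1e-15))             # monotone in iterations
})

test_that("steady and closed systems are preserved by the stepper", {
  # diffusion-only from a uniform state: state unchanged
  cfg <- list(
    compartments = list(list(name = "v", kind = "volume", tag = 1),
                        list(name = "mem", kind = "surface", tag = 2,
                             borders = list("v"))),
    species = list(list(name = "X", compartment = "v", D = 10, initial = 2)))
  m0 <- validate_model(build_containers(cfg), generate_slab(1, 1, 1, 2))
  s0 <- run_simulation(m0, t_final = 1, dt = 0.25)
  expect_equal(s0$fields[[length(s0$times)]]$X,
               rep(2, length(s0$fields[[1]]$X)), tolerance = 1e-12)

  # closed A <-> B: pointwise total conserved at every output
  m <- ab_model(A0 = 0.8, B0 = 0.4)
  s <- run_simulation(m, t_final = 1, dt = 0.02,
                      output_times = seq(0.1, 1, 0.1))
  for (k in seq_along(s$times)) {
    tot <- s$fields[[k]]$A + s$fields[[k]]$B
    expect_equal(tot, rep(1.2, length(tot)), tolerance = 1e-8)
  }
})

test_that("threshold events fire at the known crossing and latch", {
  # decay at rate kdec = 1; event freezes the decay when avg <= 0.5
  cfg <- list(
    compartments = list(list(name = "v", kind = "volume", tag = 1),
                        list(name = "mem", kind = "surface", tag = 2,
                             borders = list("v"))),
    species = list(list(name = "Ca", compartment = "v", D = 10, initial = 1)),
    parameters = list(list(name = "kdec", value = 1, kind = "prestep")),
    reactions = list(list(name = "dec", type = "volume", compartment = "v",
                          rate = "kdec*Ca", stoich = list(Ca = -1))))
  m <- validate_model(build_containers(cfg), generate_slab(1, 1, 1, 1))
  tau <- 0.05
  ev <- register_event("avg_Ca <= 0.5", "kdec", 0)
  s <- run_simulation(m, t_final = 3, dt = tau, events = list(ev))
  frozen <- compartment_average(s, "Ca")
  # discrete decay factor per step is 1/(1+tau); the event is checked at
  # the pre-step state, so the frozen value is within one step of 0.5
  expect_lte(frozen, 0.5 + 1e-12)
  expect_gte(frozen, 0.5 / (1 + tau) - 1e-12)
  expect_true(all(s$final_state$event_fired))
  # crossing step index matches the closed-form discrete crossing time
  n_star <- ceiling(log(2) / log(1 + tau))
  expect_equal(frozen, (1 + tau)^(-n_star), tolerance = 1e-10)

  # time-triggered flux shutoff: decay afterwards is pure exponential
  cfg$parameters <- list(list(name = "kdec", value = 1),
                         list(name = "Jin", value = 2, kind = "prestep"))
  cfg$reactions <- c(cfg$reactions, list(
    list(name = "influx", type = "volume_surface", compartment = "mem",
         rate = "Jin", stoich = list(Ca = 1), rate_unit = "uM*um/s")))
  m2 <- validate_model(build_containers(cfg), generate_slab(1, 1, 1, 1))
  ev2 <- register_event("t >= 1.0", "Jin", 0)
  s2 <- run_simulation(m2, t_final = 2, dt = 0.05, events = list(ev2),
                       output_times = c(1, 2))
  a1 <- compartment_average(s2, "Ca", time = 1)
  a2 <- compartment_average(s2, "Ca", time = 2)
  expect_equal(a2 / a1, (1 + 0.05)^(-20), tolerance = 1e-10)
})

test_that("scalar coupling predictor/corrector satisfies its identities", {
  mesh <- generate_slab(1, 1, 1, 2)
  base_cfg <- function(init) list(
    compartments = list(list(name = "v", kind = "volume", tag = 1),
                        list(name = "mem", kind = "surface", tag = 2,
                             borders = list("v"))),
    species = list(list(name = "F", compartment = "v", D = 10,
                        initial = init)),
    parameters = list(list(name = "Tc", value = 0.7, kind = "prestep")),
    reactions = list())

  # rate coefficient zero: scalar untouched by predictor and corrector
  m <- validate_model(build_containers(base_cfg(1)), mesh)
  sc0 <- scalar_coupling("Tc", "mem", "F", rate_coeff = 0, prefactor = 0.5,
                         value = 0.7)
  s <- run_simulation(m, t_final = 0.5, dt = 0.05, couplings = list(sc0))
  expect_identical(s$final_state$scalars$Tc, 0.7)

  # field identically equal to the scalar: both updates are identities
  m2 <- validate_model(build_containers(base_cfg(0.7)), mesh)
  sc1 <- scalar_coupling("Tc", "mem", "F", rate_coeff = 3, prefactor = 0.5,
                         value = 0.7)
  s2 <- run_simulation(m2, t_final = 0.5, dt = 0.05, couplings = list(sc1))
  expect_equal(s2$final_state$scalars$Tc, 0.7, tolerance = 1e-14)

  # clamped field: geometric relaxation at the closed-form discrete rate.
  # With a = prefactor * k * area, the predictor/corrector pair gives
  # s_{n+1} - F = (1 - tau a (1 - tau a)) (s_n - F).
  m3 <- validate_model(build_containers(base_cfg(1)), mesh)
  tau <- 0.1
  a <- 0.5 * 3 * 1
  sc2 <- scalar_coupling("Tc", "mem", "F", rate_coeff = 3, prefactor = 0.5,
                         value = 0)
  s3 <- run_simulation(m3, t_final = 1, dt = tau, couplings = list(sc2),
                       output_times = seq(tau, 1, tau))
  svals <- vapply(s3$scalars, function(x) x$Tc, 1)
  rho <- 1 - tau * a * (1 - tau * a)
  expect_equal(svals, 1 - rho^(seq_along(svals)), tolerance = 1e-12)
})

test_that("restart mediation reproduces the unrestarted trajectory", {
  # cubic sink far off the slow manifold: the first step at dt = 0.2 needs
  # more Newton iterations than the tightened budget allows and restarts
  # down to an admissible step; later steps are mild
  cfg <- list(
    compartments = list(list(name = "v", kind = "volume", tag = 1),
                        list(name = "mem", kind = "surface", tag = 2,
                             borders = list("v"))),
    species = list(list(name = "X", compartment = "v", D = 1, initial = 20)),
    parameters = list(list(name = "kg", value = 5)),
    reactions = list(list(name = "nl", type = "volume", compartment = "v",
                          rate = "kg*X*X*X", stoich = list(X = -1))))
  m <- validate_model(build_containers(cfg), generate_slab(1, 1, 1, 1))
  tight <- run_simulation(m, t_final = 1.6, dt = 0.2,
                          settings = solver_settings(newton_max = 7L))
  expect_gt(sum(tight$log$restarts), 0)
  tau_used <- tight$log$tau[1]
  expect_lt(tau_used, 0.2)
  # restarts hit only the first step, so the accepted grid is uniform and
  # comparable to an unrestarted run at the reduced step
  expect_lt(max(abs(tight$log$tau - tau_used)), 1e-12)
  base <- run_simulation(m, t_final = 1.6, dt = tau_used)
  expect_equal(tight$fields[[length(tight$times)]]$X,
               base$fields[[length(base$times)]]$X, tolerance = 1e-8)
})

test_that("implicit Euler is first order on a fixed mesh before the spatial floor", {
  r <- convergence_study(slab_problem(D = 10), "tau", levels = 3,
                         n_fixed = 4, tau0 = 0.4, t_final = 4)
  expect_gt(r$fitted_order, 0.9)
  expect_lt(r$fitted_order, 1.2)
  expect_true(all(diff(r$table$error) < 0))
})
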