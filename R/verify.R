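# Verification suite: analytic slab benchmark, L2 errors, convergence
# studies and the well-mixed (ODE) limit check.
#
# Analytic steady state of the slab benchmark.  With equal diffusivities
# and a uniform initial total, A + Ap = A_tot holds pointwise at steady
# state, so the phosphorylated form solves
#     D Ap'' = k_p Ap            on (0, L)
#     -D Ap'(0) = k_kin (A_tot - Ap(0))     (membrane influx at z = 0)
#      Ap'(L) = 0                           (no-flux at z = L)
# giving  Ap(z) = C cosh((L - z)/lambda),  lambda = sqrt(D / k_p),
#         C = k_kin A_tot / ( (D/lambda) sinh(L/lambda)
#                             + k_kin cosh(L/lambda) ).

#' Analytic steady-state solution of the slab benchmark
#'
#' @param problem a [slab_problem()].
#' @return list of functions `Ap(z)`, `A(z)` (vectorized over the thickness
#'   coordinate) and the constants `lambda`, `C`.
#' @export
analytic_slab <- function(problem) {
  stopifnot(inherits(problem, "slab_problem"))
  lam <- sqrt(problem$D / problem$k_p)
  Lr <- problem$L / lam
  C <- problem$k_kin * problem$A_tot /
    ((problem$D / lam) * sinh(Lr) + problem$k_kin * cosh(Lr))
  Ap <- function(z) C * cosh((problem$L - z) / lam)
  list(Ap = Ap,
       A = function(z) problem$A_tot - Ap(z),
       lambda = lam, C = C)
}

#' L2 norm of the difference between a P1 field and an exact solution
#'
#' `|| u_h - u_e ||_{L2(compartment)}` with per-element quadrature exact
#' for degree-2 integrands (degree-3 on edges).
#'
#' @param sub a `submesh_view`.
#' @param nodal nodal values of the P1 field on the submesh.
#' @param exact function of the coordinate matrix returning exact values.
#' @param weight optional quadrature weight (axisymmetric radius).
#' @return the L2 error (same units as the field).
#' @export
l2_error <- function(sub, nodal, exact, weight = NULL) {
  ents <- sub$entities
  m <- ncol(ents)
  coords <- submesh_coords(sub)
  q <- .quad_rule(m)
  total <- 0
  wv <- if (is.null(weight)) NULL else rep(weight, length.out = sub$n_vertices)
  for (k in seq_len(nrow(q$bary))) {
    lam <- q$bary[k, ]
    pts <- matrix(0, nrow(ents), ncol(coords))
    uh <- numeric(nrow(ents))
    for (i in seq_len(m)) {
      pts <- pts + lam[i] * coords[ents[, i], , drop = FALSE]
      uh <- uh + lam[i] * nodal[ents[, i]]
    }
    diff2 <- (uh - exact(pts))^2
    if (!is.null(wv)) {
      wq <- numeric(nrow(ents))
      for (i in seq_len(m)) wq <- wq + lam[i] * wv[ents[, i]]
      diff2 <- diff2 * wq
    }
    total <- total + sum(q$w[k] * sub$measures * diff2)
  }
  sqrt(total)
}

# run the (linear) slab model to steady state quickly: large fixed step so
# the cached factorization is reused; steady state of implicit Euler is the
# steady state of the spatial discretization, independent of tau
.slab_steady <- function(problem, n, tau = 5, settings = solver_settings()) {
  model <- slab_model(problem, n)
  run_simulation(model, t_final = 1e4, dt = tau, adaptive = FALSE,
                 settings = settings, steady_tol = 1e-10)
}

#' Mesh or time-step convergence study on the slab benchmark
#'
#' `mode = "h"`: uniform refinements solved to steady state; L2 errors of
#' the phosphorylated form against the analytic profile; expected order 2.
#' `mode = "tau"`: fixed mesh, `tau` halved per level, all runs to
#' `t_final`; errors against a reference trajectory on the same mesh at
#' `tau_min / 16` (self-convergence, isolating the temporal error;
#' expected order 1), plus errors against the analytic steady profile
#' whose flattening marks the spatial-error plateau.
#'
#' @param problem a [slab_problem()].
#' @param mode `"h"` or `"tau"`.
#' @param levels number of refinement levels (>= 3).
#' @param n0 coarsest mesh resolution (mode "h").
#' @param n_fixed mesh resolution for mode "tau".
#' @param tau0 coarsest time step (s, mode "tau").
#' @param t_final end time for mode "tau" (s).  Chosen so the continuous
#'   transient has largely decayed while the backward-Euler lag of a coarse
#'   tau has not: the error against the steady profile then falls first
#'   order in tau before flattening at the spatial floor.
#' @return a `convergence_report`: data frame of levels (`h` or `tau`),
#'   errors, pairwise orders, plus `fitted_order` (least squares) and, for
#'   mode "tau", `error_vs_analytic` and `plateau_onset`.
#' @export
convergence_study <- function(problem = slab_problem(), mode = c("h", "tau"),
                              levels = 4, n0 = 2, n_fixed = 8,
                              tau0 = 0.5, t_final = 8) {
  mode <- match.arg(mode)
  stopifnot(levels >= 3)
  exact <- analytic_slab(problem)
  if (mode == "h") {
    hs <- errs <- numeric(levels)
    for (lv in seq_len(levels)) {
      n <- n0 * 2^(lv - 1)
      series <- .slab_steady(problem, n)
      sub <- series$model$submeshes$cytosol
      errs[lv] <- l2_error(sub, series$fields[[length(series$times)]]$Ap,
                           function(p) exact$Ap(p[, 3]))
      hs[lv] <- problem$L / n
    }
    lev <- hs
  } else {
    taus <- tau0 / 2^(seq_len(levels) - 1)
    model <- slab_model(problem, n_fixed)
    # temporal order is measured during the active transient (t_order),
    # where the backward-Euler global error is O(tau); the plateau against
    # the analytic steady profile is measured at t_final
    t_order <- min(2 / problem$k_p, t_final)
    run_at <- function(tau) {
      run_simulation(model, t_final = t_final, dt = tau, adaptive = FALSE,
                     output_times = c(t_order, t_final))
    }
    ref <- run_at(taus[levels] / 16)
    ref_field <- ref$fields[[1]]$Ap
    sub <- model$submeshes$cytosol
    Msub <- assemble_mass(sub)
    errs <- errs_an <- numeric(levels)
    for (lv in seq_len(levels)) {
      series <- run_at(taus[lv])
      dv <- series$fields[[1]]$Ap - ref_field
      errs[lv] <- sqrt(as.numeric(t(dv) %*% (Msub %*% dv)))
      errs_an[lv] <- l2_error(sub, series$fields[[length(series$times)]]$Ap,
                              function(p) exact$Ap(p[, 3]))
    }
    lev <- taus
  }
  pair_order <- c(NA, log(errs[-length(errs)] / errs[-1]) /
                      log(lev[-length(lev)] / lev[-1]))
  fit <- stats::lm(log(errs) ~ log(lev))
  report <- list(
    mode = mode,
    table = data.frame(level = lev, error = errs, pairwise_order = pair_order),
    fitted_order = unname(stats::coef(fit)[2]),
    problem = problem)
  if (mode == "tau") {
    report$error_vs_analytic <- errs_an
    floor_err <- errs_an[levels]
    plateau <- lev[errs_an <= 1.10 * floor_err]
    report$plateau_onset <- if (length(plateau)) max(plateau) else lev[levels]
  }
  structure(report, class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence_report: mode %s, fitted order %.3f>\n",
              x$mode, x$fitted_order))
  print(x$table, row.names = FALSE)
  if (!is.null(x$plateau_onset)) {
    cat(sprintf("  plateau onset tau (vs analytic steady profile): %.4g\n",
                x$plateau_onset))
  }
  invisible(x)
}

#' Deviation of the PDE solution from its well-mixed ODE reduction
#'
#' Re-validates the model with every volume diffusivity set to `D_large`
#' (surface species made uniform and non-diffusing), runs the PDE, runs
#' the reduced ODE with a standard stiff integrator, and returns the
#' maximum over output times and species of the relative deviation of
#' compartment averages.
#'
#' @param model an `rd_model` without space-expression parameters.
#' @param D_large diffusivity for all volume species (um^2 s^-1).
#' @param t_final,dt simulation horizon and PDE time step (s).
#' @param n_out number of comparison times.
#' @return list `deviation` (max relative deviation), `table` (per-time
#'   averages of both routes).
#' @export
ode_limit_check <- function(model, D_large = 1000, t_final = 1, dt = 0.01,
                            n_out = 10) {
  cont <- model$containers
  for (nm in names(cont$species)) {
    cp <- cont$species[[nm]]$compartment
    if (model$compartments[[cp]]$kind == "volume") {
      cont$species[[nm]]$D <- D_large
    } else {
      cont$species[[nm]]$D <- 0
    }
  }
  fast <- validate_model(cont, model$mesh, axisymmetric = model$axisymmetric)
  times <- seq(t_final / n_out, t_final, length.out = n_out)
  series <- run_simulation(fast, t_final = t_final, dt = dt,
                           output_times = times)
  ode <- reduce_to_ode(fast)
  ode_fun <- function(t, y, parms) list(unname(ode$rhs(t, y)))
  sol <- deSolve::lsoda(y = ode$y0, times = c(0, times), func = ode_fun,
                        rtol = 1e-10, atol = 1e-12)
  dev <- 0
  tab <- list()
  for (k in seq_along(series$times)) {
    tk <- series$times[k]
    j <- which.min(abs(sol[, "time"] - tk))
    for (nm in names(fast$species)) {
      pde_avg <- compartment_average(series, nm, state = series$fields[[k]][[nm]])
      ode_avg <- sol[j, nm]
      scale <- max(abs(ode_avg), 1e-12 * max(abs(ode$y0)))
      dev <- max(dev, abs(pde_avg - ode_avg) / scale)
      tab[[length(tab) + 1L]] <- data.frame(time = tk, species = nm,
                                            pde = pde_avg, ode = ode_avg)
    }
  }
  list(deviation = dev, table = do.call(rbind, tab))
}
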