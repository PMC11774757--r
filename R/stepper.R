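# Monolithic implicit-Euler time integration.
#
# Each step solves M (u^{n+1} - u^n) / tau = -K u^{n+1} + L(u^{n+1}, t_{n+1})
# by Newton-Raphson with the exact symbolic Jacobian, via a sparse direct
# factorization.  Step control: adaptive tau from the previous Newton
# iteration count; on divergence or negative concentrations the step
# restarts with a reduced tau.  Pre-step: time parameters advance, scalar
# couplings apply their predictor, threshold events fire.  Post-step:
# scalar correctors run once per accepted step.

#' Solver settings
#'
#' @param newton_atol,newton_rtol absolute / relative residual tolerances
#'   (2-norm) for Newton convergence.
#' @param newton_max maximum Newton iterations per step.
#' @param dt_min,dt_max bounds on the time step (s).
#' @param grow_iters,grow_factor grow tau by `grow_factor` when the
#'   previous step converged in at most `grow_iters` iterations.
#' @param shrink_iters,shrink_factor shrink tau when at least
#'   `shrink_iters` iterations were needed.
#' @param restart_factor,max_restarts tau multiplier and retry budget when
#'   a step diverges or produces negative concentrations.
#' @param negativity_tol concentrations below `-negativity_tol` times the
#'   species scale trigger a restart; tiny negatives are clamped at output
#'   only, never in-state.
#' @export
solver_settings <- function(newton_atol = 1e-10, newton_rtol = 1e-8,
                            newton_max = 25L,
                            dt_min = 1e-12, dt_max = Inf,
                            grow_iters = 3L, grow_factor = 1.25,
                            shrink_iters = 8L, shrink_factor = 0.7,
                            restart_factor = 0.5, max_restarts = 10L,
                            negativity_tol = 1e-8) {
  as.list(environment())
}

#' Newton-Raphson solve of one implicit-Euler step equation
#'
#' @param sys a block system from `build_system()` (internal).
#' @param u_guess starting iterate (finite).
#' @param u_prev previous accepted state.
#' @param tau time step (s).
#' @param t_next target time (s).
#' @param param_state named list of current constant/prestep parameter
#'   values.
#' @return list `u` (converged iterate), `iterations`, `residual`.
#' @export
newton_solve <- function(sys, u_guess, u_prev, tau, t_next, param_state) {
  st <- sys$settings
  u <- u_guess
  if (any(!is.finite(u))) stop("non-finite Newton guess", call. = FALSE)
  eval_at <- .newton_solver(sys, u, u_prev, tau, t_next, param_state)
  res <- eval_at(u)
  r0 <- sqrt(sum(res$F^2))
  rprev <- r0
  tol <- max(st$newton_atol, st$newton_rtol * r0)
  if (r0 <= st$newton_atol) {
    return(list(u = u, iterations = 0L, residual = r0))
  }
  for (it in seq_len(st$newton_max)) {
    du <- tryCatch(res$solve(res$F), error = function(e) rep(NaN, length(u)))
    u <- u - du
    if (any(!is.finite(u))) {
      stop("nonlinear-divergence error: Newton iterate became non-finite",
           call. = FALSE)
    }
    res <- eval_at(u)
    r <- sqrt(sum(res$F^2))
    if (!is.finite(r)) {
      stop("nonlinear-divergence error: residual is NaN", call. = FALSE)
    }
    if (r <= tol) {
      return(list(u = u, iterations = it, residual = r))
    }
    if (it > 3L && r > 10 * rprev) {
      stop("nonlinear-divergence error: residual diverging", call. = FALSE)
    }
    rprev <- r
  }
  stop(sprintf("nonlinear-divergence error: no convergence in %d iterations (residual %.3e)",
               st$newton_max, sqrt(sum(res$F^2))), call. = FALSE)
}

#' Adapt the time step from the previous Newton iteration count
#'
#' Monotone policy: grow by `grow_factor` when iterations were at most
#' `grow_iters`, shrink by `shrink_factor` when at least `shrink_iters`,
#' hold otherwise; always clamped to `[dt_min, dt_max]`.
#'
#' @param iterations Newton iterations of the accepted step.
#' @param tau current step (s).
#' @param settings a [solver_settings()] list.
#' @return next tau.
#' @export
adapt_dt <- function(iterations, tau, settings = solver_settings()) {
  s <- settings
  tau_new <- if (iterations <= s$grow_iters) tau * s$grow_factor
             else if (iterations >= s$shrink_iters) tau * s$shrink_factor
             else tau
  min(max(tau_new, s$dt_min), s$dt_max)
}

#' Register a threshold event
#'
#' The condition is an expression over `t`, scalar-coupling values, current
#' constant/prestep parameters, and per-species compartment averages
#' exposed as `avg_<species>`.  When it first becomes true at a pre-step
#' check, the action assigns `value` to the named parameter; latching
#' events fire at most once.
#'
#' @param condition expression string, e.g. `"avg_Ca >= 0.5"` or
#'   `"t >= 1.0"`.
#' @param param name of a declared (constant or prestep) parameter.
#' @param value number assigned when the event fires.
#' @param repeating if `TRUE` the condition is re-armed after firing.
#' @param name optional label for the step log.
#' @return an `rd_event` handle (pass a list of these to
#'   [run_simulation()]).
#' @export
register_event <- function(condition, param, value, repeating = FALSE,
                           name = NULL) {
  cond <- tryCatch(str2lang(condition), error = function(e) {
    stop(sprintf("cannot parse event condition '%s'", condition), call. = FALSE)
  })
  structure(list(condition = cond, condition_text = condition, param = param,
                 value = value, repeating = repeating,
                 name = if (is.null(name)) condition else name),
            class = "rd_event")
}

#' Declare a well-mixed scalar coupled through a surface integral
#'
#' Implements the pre/post-step coupling of a 0D pool to a PDE field: before
#' each step the scalar `s` is advanced by a predictor
#' `s_est = s + tau * prefactor * int_G k (field - s) dG`, the PDEs are
#' solved with `s_est` bound to the declared parameter, and after the solve
#' the corrector repeats the update using the post-solve field and `s_est`
#' in the integrand.  `prefactor` carries the volume and unit scalings
#' (e.g. `1 / (vol * N_A)` with the mM um^3 mol^-1 conversion); `rate_coeff`
#' is the transport coefficient times the channel surface density.
#'
#' @param name scalar name; must match a declared `prestep` parameter,
#'   whose value tracks the scalar during the run.
#' @param surface surface compartment name over which the flux integral
#'   runs.
#' @param field volume species whose trace drives the exchange.
#' @param rate_coeff numeric transport coefficient (per concentration
#'   difference, per area).
#' @param prefactor numeric scaling from integrated flux to d(scalar)/dt.
#' @param value initial scalar value.
#' @export
scalar_coupling <- function(name, surface, field, rate_coeff, prefactor,
                            value) {
  structure(list(name = name, surface = surface, field = field,
                 rate_coeff = rate_coeff, prefactor = prefactor,
                 value = value), class = "rd_scalar_coupling")
}

# integral term: prefactor * int_G k (field - s) dG with lumped quadrature
.scalar_flux <- function(sys, sc, u, s_value) {
  model <- sys$model
  sub <- model$submeshes[[sc$surface]]
  lump <- sys$comp_lump[[sc$surface]]
  g <- model$submeshes[[model$species[[sc$field]]$compartment]]
  vol_local <- integer(nrow(model$mesh$vertices))
  vol_local[g$vertex_parent] <- seq_along(g$vertex_parent)
  idx <- vol_local[sub$vertex_parent]
  fld <- u[sys$dof$offset[[sc$field]] + idx]
  sc$prefactor * sum(lump * sc$rate_coeff * (fld - s_value))
}

# compartment averages of every species (consistent mass quadrature)
.all_averages <- function(sys, u) {
  model <- sys$model
  out <- numeric(length(model$species))
  names(out) <- names(model$species)
  for (nm in names(model$species)) {
    cn <- model$species[[nm]]$compartment
    lm <- sys$comp_lump[[cn]]
    out[nm] <- sum(lm * u[species_slice(sys$dof, nm)]) / sum(lm)
  }
  out
}

.event_env <- function(sys, u, t, param_state, scalar_values) {
  env <- c(list(t = t, pi = pi), param_state, as.list(scalar_values))
  av <- .all_averages(sys, u)
  names(av) <- paste0("avg_", names(av))
  c(env, as.list(av))
}

#' Advance the system by one (possibly restarted) implicit-Euler step
#'
#' Runs the full pre-step / solve / post-step sequence: time parameters are
#' evaluated at `t + tau`, scalar-coupling predictors and events are
#' applied, the nonlinear system is solved, correctors run, and on
#' divergence or negative concentrations beyond tolerance the step is
#' retried with `tau * restart_factor`, up to `max_restarts` times.
#'
#' @param sys block system (internal; see [run_simulation()] for the
#'   user-facing driver).
#' @param state list with `u`, `t`, `tau`, `param_state`, `scalars`,
#'   `event_fired`.
#' @param events list of [register_event()] handles.
#' @param couplings list of [scalar_coupling()] declarations.
#' @return updated state, with a `log` record of the accepted step.
#' @export
advance_step <- function(sys, state, events = list(), couplings = list()) {
  st <- sys$settings
  tau <- state$tau
  restarts <- 0L
  scale <- max(abs(state$u), 1)
  repeat {
    param_state <- state$param_state
    scalars <- state$scalars
    event_fired <- state$event_fired
    t_next <- state$t + tau

    # --- pre-step -------------------------------------------------------
    # events (latched by default), checked on the state at t_n
    ev_env <- .event_env(sys, state$u, state$t, param_state, scalars)
    for (k in seq_along(events)) {
      ev <- events[[k]]
      if (!ev$repeating && isTRUE(event_fired[[k]])) next
      on <- isTRUE(eval(ev$condition, envir = ev_env, enclos = baseenv()))
      if (on) {
        param_state[[ev$param]] <- ev$value
        event_fired[[k]] <- TRUE
      }
    }
    # scalar predictors (estimate at t_n + tau from the state at t_n)
    est <- scalars
    for (sc in couplings) {
      est[[sc$name]] <- scalars[[sc$name]] +
        tau * .scalar_flux(sys, sc, state$u, scalars[[sc$name]])
      param_state[[sc$name]] <- est[[sc$name]]
    }

    # --- solve ----------------------------------------------------------
    sol <- tryCatch(
      newton_solve(sys, state$u, state$u, tau, t_next, param_state),
      error = function(e) e)
    ok <- !inherits(sol, "error")
    if (ok && min(sol$u) < -st$negativity_tol * scale) ok <- FALSE
    if (!ok) {
      restarts <- restarts + 1L
      if (restarts > st$max_restarts) {
        msg <- if (inherits(sol, "error")) conditionMessage(sol)
               else "negative concentrations"
        stop(sprintf("step-failure error at t = %.6g after %d restarts: %s",
                     state$t, st$max_restarts, msg), call. = FALSE)
      }
      tau <- max(tau * st$restart_factor, st$dt_min)
      next
    }

    # --- post-step ------------------------------------------------------
    # correctors: re-evaluate the flux with the implicit field and the
    # predictor estimate, once per accepted step
    for (sc in couplings) {
      scalars[[sc$name]] <- scalars[[sc$name]] +
        tau * .scalar_flux(sys, sc, sol$u, est[[sc$name]])
      param_state[[sc$name]] <- scalars[[sc$name]]
    }
    new_tau <- adapt_dt(sol$iterations, tau, st)
    return(list(u = sol$u, t = t_next, tau = new_tau,
                param_state = param_state, scalars = scalars,
                event_fired = event_fired,
                log = list(t = t_next, tau = tau,
                           iterations = sol$iterations,
                           restarts = restarts, residual = sol$residual)))
  }
}

#' Run a simulation
#'
#' Drives the implicit-Euler / Newton loop from `t = 0` to `t_final`,
#' storing species fields at the accepted steps nearest (not exceeding)
#' each requested output time, plus a per-step log.  Deterministic given
#' the model and settings.
#'
#' @param model an `rd_model`.
#' @param t_final end time (s), > 0.
#' @param dt initial time step (s).
#' @param adaptive if `TRUE`, tau adapts to Newton iteration counts within
#'   `[dt_min, dt_max]`; otherwise tau stays fixed at `dt` (up to restart
#'   reductions).
#' @param output_times times at which to store fields (step-aligned, no
#'   interpolation); defaults to `t_final` only.
#' @param settings a [solver_settings()] list.
#' @param events list of [register_event()] handles.
#' @param couplings list of [scalar_coupling()] declarations.
#' @param steady_tol if positive, stop early once the relative change of
#'   the state per unit time drops below this (steady state detection).
#' @return an object of class `solution_series`: `times`, `fields` (list of
#'   per-output named lists of nodal vectors), `scalars`, `log` (data
#'   frame), `model`.
#' @export
run_simulation <- function(model, t_final, dt, adaptive = FALSE,
                           output_times = NULL, settings = solver_settings(),
                           events = list(), couplings = list(),
                           steady_tol = 0) {
  stopifnot(inherits(model, "rd_model"), t_final > 0, dt > 0)
  if (!adaptive) {
    settings$grow_factor <- 1
    settings$shrink_factor <- 1
  }
  sys <- build_system(model, settings)
  if (is.null(output_times)) output_times <- t_final
  output_times <- sort(unique(output_times))

  param_state <- list()
  for (pm in model$parameters) {
    if (pm$kind %in% c("constant", "prestep")) param_state[[pm$name]] <- pm$value
  }
  scalars <- list()
  for (sc in couplings) {
    scalars[[sc$name]] <- sc$value
    param_state[[sc$name]] <- sc$value
  }
  state <- list(u = model_initial_state(model), t = 0, tau = dt,
                param_state = param_state, scalars = scalars,
                event_fired = rep(FALSE, length(events)))

  out_times <- numeric(0)
  out_fields <- list()
  out_scalars <- list()
  logs <- list()
  next_out <- 1L
  store <- function(state) {
    dofl <- sys$dof
    fields <- list()
    for (nm in names(model$species)) {
      v <- state$u[species_slice(dofl, nm)]
      v[v < 0 & v > -sys$settings$negativity_tol * max(abs(v), 1)] <- 0
      fields[[nm]] <- v
    }
    fields
  }
  # store t = 0 if requested
  while (next_out <= length(output_times) && output_times[next_out] <= 0) {
    out_times <- c(out_times, 0)
    out_fields[[length(out_fields) + 1L]] <- store(state)
    out_scalars[[length(out_scalars) + 1L]] <- scalars
    next_out <- next_out + 1L
  }

  prev_norm <- sqrt(sum(state$u^2))
  while (state$t < t_final - 1e-12 * t_final) {
    # do not step past t_final or the next output time
    tau_cap <- t_final - state$t
    if (next_out <= length(output_times)) {
      tau_cap <- min(tau_cap, output_times[next_out] - state$t)
    }
    state$tau <- min(state$tau, tau_cap)
    new <- advance_step(sys, state, events, couplings)
    logs[[length(logs) + 1L]] <- new$log
    tau_used <- new$log$tau
    state <- new
    while (next_out <= length(output_times) &&
           state$t >= output_times[next_out] - 1e-9 * max(output_times[next_out], 1)) {
      out_times <- c(out_times, state$t)
      out_fields[[length(out_fields) + 1L]] <- store(state)
      out_scalars[[length(out_scalars) + 1L]] <- state$scalars
      next_out <- next_out + 1L
    }
    if (steady_tol > 0) {
      nrm <- sqrt(sum(state$u^2))
      rate <- abs(nrm - prev_norm) / max(nrm, 1e-300) / tau_used
      prev_norm <- nrm
      if (rate < steady_tol) break
    }
  }
  if (!length(out_times) || out_times[length(out_times)] < state$t) {
    out_times <- c(out_times, state$t)
    out_fields[[length(out_fields) + 1L]] <- store(state)
    out_scalars[[length(out_scalars) + 1L]] <- state$scalars
  }
  log_df <- do.call(rbind, lapply(logs, as.data.frame))
  structure(list(times = out_times, fields = out_fields,
                 scalars = out_scalars, log = log_df,
                 final_state = state, model = model, system = sys),
            class = "solution_series")
}

#' @export
print.solution_series <- function(x, ...) {
  cat(sprintf("<solution_series: %d outputs to t = %.6g, %d steps, %d species>\n",
              length(x$times), max(x$times), nrow(x$log),
              length(x$model$species)))
  invisible(x)
}

#' @export
summary.solution_series <- function(object, ...) {
  cat(sprintf("Simulation to t = %.6g s (%d accepted steps)\n",
              max(object$times), nrow(object$log)))
  cat(sprintf("  Newton iterations: median %g, max %g; restarts: %d\n",
              stats::median(object$log$iterations), max(object$log$iterations),
              sum(object$log$restarts)))
  av <- .all_averages(object$system, object$final_state$u)
  for (nm in names(av)) {
    cat(sprintf("  final average %-12s %.8g\n", nm, av[[nm]]))
  }
  invisible(object)
}
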