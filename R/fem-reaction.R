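# Block system assembly.
#
# build_system() precomputes per-species mass and stiffness blocks, lumped
# quadrature weights and trace index maps; assemble_reaction() evaluates
# all reaction terms (volume sources f, surface sources g, boundary fluxes
# R) at a given state and time with vertex (mass-lumped) quadrature,
# returning the Galerkin load vector and exact Jacobian triplets from the
# symbolic derivatives.
#
# Sign and unit conventions (fixed):
#   * positive rate x positive stoichiometry = production / influx;
#   * boundary fluxes are integrated over the surface; the volume side
#     receives them in uM um s^-1 (rate / 602.214076), the surface side in
#     molecules um^-2 s^-1;
#   * D grad(u) . n = -R with n outward from the volume, so positive R is
#     flux INTO the volume.

build_system <- function(model, settings = solver_settings()) {
  dof <- model_dofmap(model)
  w_of <- function(sub) {
    if (is.null(model$weight)) NULL else model$weight[sub$vertex_parent]
  }
  comp_mass <- list(); comp_lump <- list()
  for (cn in names(model$compartments)) {
    sub <- model$submeshes[[cn]]
    comp_mass[[cn]] <- assemble_mass(sub, w_of(sub))
    comp_lump[[cn]] <- as.numeric(Matrix::rowSums(comp_mass[[cn]]))
  }
  Mblocks <- list(); Kblocks <- list()
  for (nm in names(model$species)) {
    sp <- model$species[[nm]]
    sub <- model$submeshes[[sp$compartment]]
    Mblocks[[nm]] <- comp_mass[[sp$compartment]]
    Kblocks[[nm]] <- assemble_stiffness(sub, sp$D, w_of(sub))
  }
  M <- Matrix::bdiag(Mblocks)
  K <- Matrix::bdiag(Kblocks)

  # reaction evaluation contexts
  sp_comp <- vapply(model$species, `[[`, "", "compartment")
  comp_kind <- vapply(model$compartments, `[[`, "", "kind")
  ctxs <- list()
  for (rn in names(model$reactions)) {
    rx <- model$reactions[[rn]]
    bind <- rx$spec$compartment
    sub <- model$submeshes[[bind]]
    coords <- submesh_coords(sub)
    lump <- comp_lump[[bind]]
    # gather map for every species symbol appearing in rate or stoich
    sp_all <- union(rx$rate$species_used, names(rx$spec$stoich))
    gather <- list()
    for (snm in sp_all) {
      scomp <- sp_comp[[snm]]
      if (scomp == bind) {
        idx <- seq_len(sub$n_vertices)
      } else {
        # volume species seen from the binding surface: trace by parent vertex
        vol_sub <- model$submeshes[[scomp]]
        vol_local <- integer(nrow(model$mesh$vertices))
        vol_local[vol_sub$vertex_parent] <- seq_along(vol_sub$vertex_parent)
        idx <- vol_local[sub$vertex_parent]
        if (any(idx == 0L)) {
          stop(sprintf("mesh consistency error: surface '%s' vertex missing from volume '%s'",
                       bind, scomp), call. = FALSE)
        }
      }
      gather[[snm]] <- list(offset = dof$offset[[snm]], idx = idx,
                            kind = comp_kind[[scomp]])
    }
    # per-stoich-species row map and unit factor
    targets <- list()
    for (snm in names(rx$spec$stoich)) {
      g <- gather[[snm]]
      fac <- rx$spec$stoich[[snm]] * rx$conv
      if (rx$spec$type != "volume" && g$kind == "volume") {
        fac <- fac / MOLECULES_PER_UM3_PER_MICROMOLAR
      }
      targets[[snm]] <- list(rows = g$offset + g$idx, factor = fac)
    }
    ctxs[[rn]] <- list(name = rn, rate = rx$rate, type = rx$spec$type,
                       bind = bind, coords = coords, lump = lump,
                       gather = gather, targets = targets)
  }

  # a model is "linear with constant Jacobian" when every rate derivative
  # involves only constant parameters: the step matrix then depends on tau
  # alone and its factorization can be reused across steps
  const_pars <- names(model$parameters)[vapply(model$parameters, function(p)
    p$kind == "constant", TRUE)]
  linear_const <- all(vapply(model$reactions, function(rx) {
    all(vapply(rx$rate$deriv, function(d) {
      syms <- setdiff(all.vars(d), c(const_pars, "pi"))
      length(syms) == 0L
    }, TRUE))
  }, TRUE))

  list(model = model, dof = dof, M = M, K = K,
       comp_mass = comp_mass, comp_lump = comp_lump,
       Kblocks = Kblocks, contexts = ctxs, settings = settings,
       linear_const = linear_const, cache = new.env(parent = emptyenv()))
}

# parameter environment at time t; param_state carries current values of
# constant and prestep parameters (events/scalar couplings mutate it)
param_env_at <- function(model, t, param_state) {
  env <- list(t = t, pi = pi)
  for (pm in model$parameters) {
    env[[pm$name]] <- switch(pm$kind,
      constant = ,
      prestep = param_state[[pm$name]],
      time = eval(str2lang(pm$value), envir = env, enclos = baseenv()),
      space = NA)  # filled per-context below
    }
  env
}

.space_params_at <- function(model, coords, env) {
  for (pm in model$parameters) {
    if (pm$kind == "space") {
      env[[pm$name]] <- .eval_spatial(pm$value, coords)
    }
  }
  env
}

# evaluate all reaction loads and Jacobian triplets at state u, time t
assemble_reaction <- function(sys, u, t, param_state) {
  model <- sys$model
  load <- numeric(sys$dof$total)
  ti <- list(i = list(), j = list(), x = list())
  base_env <- param_env_at(model, t, param_state)
  for (ctx in sys$contexts) {
    env <- base_env
    env <- .space_params_at(model, ctx$coords, env)
    env$x <- ctx$coords[, 1]
    env$y <- if (ncol(ctx$coords) >= 2) ctx$coords[, 2] else 0
    env$z <- if (ncol(ctx$coords) >= 3) ctx$coords[, 3] else 0
    env$r <- ctx$coords[, 1]
    for (snm in names(ctx$gather)) {
      g <- ctx$gather[[snm]]
      env[[snm]] <- u[g$offset + g$idx]
    }
    vals <- tryCatch(eval_rate(ctx$rate$expr, env),
                     error = function(e) {
                       stop(sprintf("evaluation error in reaction '%s': %s",
                                    ctx$name, conditionMessage(e)), call. = FALSE)
                     })
    vals <- rep_len(vals, length(ctx$lump))
    wq <- ctx$lump * vals
    derivs <- lapply(ctx$rate$deriv, function(d) {
      rep_len(eval_rate(d, env), length(ctx$lump))
    })
    for (snm in names(ctx$targets)) {
      tg <- ctx$targets[[snm]]
      load[tg$rows] <- load[tg$rows] + tg$factor * wq
      for (dn in names(derivs)) {
        g <- ctx$gather[[dn]]
        ti$i[[length(ti$i) + 1L]] <- tg$rows
        ti$j[[length(ti$j) + 1L]] <- g$offset + g$idx
        ti$x[[length(ti$x) + 1L]] <- tg$factor * ctx$lump * derivs[[dn]]
      }
    }
  }
  list(load = load, jac = ti)
}

# residual and Jacobian of the implicit-Euler step equation
#   F(u) = M (u - u_prev) + tau K u - tau L(u, t)
step_residual <- function(sys, u, u_prev, tau, t, param_state,
                          need_jac = TRUE) {
  rx <- assemble_reaction(sys, u, t, param_state)
  F <- as.numeric(sys$M %*% (u - u_prev) + tau * (sys$K %*% u)) - tau * rx$load
  J <- NULL
  if (need_jac) {
    Jr <- if (length(rx$jac$i)) {
      Matrix::sparseMatrix(i = unlist(rx$jac$i), j = unlist(rx$jac$j),
                           x = unlist(rx$jac$x),
                           dims = c(sys$dof$total, sys$dof$total))
    } else {
      Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                           dims = c(sys$dof$total, sys$dof$total))
    }
    J <- sys$M + tau * sys$K - tau * Jr
  }
  list(F = F, J = J)
}

# linear solver for the Newton update: direct sparse LU, with the
# factorization cached across steps for linear constant-Jacobian systems
.newton_solver <- function(sys, u, u_prev, tau, t, param_state) {
  if (!isTRUE(sys$linear_const)) {
    return(function(u_cur) {
      res <- step_residual(sys, u_cur, u_prev, tau, t, param_state)
      list(F = res$F, solve = function(b) as.numeric(Matrix::solve(res$J, b)))
    })
  }
  key <- paste(format(tau, digits = 17),
               paste(names(param_state), vapply(param_state, format, "",
                                                digits = 17),
                     collapse = ";"))
  if (is.null(sys$cache$fact) || !identical(sys$cache$key, key)) {
    res <- step_residual(sys, u, u_prev, tau, t, param_state, need_jac = TRUE)
    sys$cache$fact <- Matrix::lu(res$J)
    sys$cache$key <- key
  }
  fact <- sys$cache$fact
  function(u_cur) {
    res <- step_residual(sys, u_cur, u_prev, tau, t, param_state,
                         need_jac = FALSE)
    list(F = res$F, solve = function(b) as.numeric(Matrix::solve(fact, b)))
  }
}
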