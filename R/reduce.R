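# Model reductions.
#
# (1) Conservation-law elimination: a linear combination of species that is
# unchanged by every reaction, whose members share one compartment and one
# diffusion coefficient and receive no boundary flux, and whose initial
# value is spatially uniform, stays uniform and constant; one member per
# independent combination can be eliminated and reconstructed algebraically.
# Detection is linear-algebraic (left null space of the stoichiometry
# matrix restricted to eligible species), not name-based.
#
# (2) Well-mixed (0D) reduction: one state per species, boundary fluxes
# scaled by surface/volume measure ratios with the same unit conversions as
# the PDE assembly.

# species that no surface-bound reaction reaches through its stoichiometry
.boundary_touched <- function(model) {
  touched <- character()
  for (rx in model$reactions) {
    if (rx$spec$type != "volume") {
      touched <- union(touched, names(rx$spec$stoich))
    }
  }
  touched
}

#' Eliminate species determined by conservation laws
#'
#' Finds all independent conserved linear combinations among eligible
#' species (same compartment, same diffusivity, not in the stoichiometry of
#' any surface-bound reaction, spatially uniform initial combination) and
#' eliminates one species per combination, substituting
#' `(total - other members)` into every rate expression.  The reduced model
#' carries a reconstruction map and produces trajectories identical to the
#' unreduced model.
#'
#' @param model an `rd_model`.
#' @return the reduced `rd_model` (unchanged if no conservation law
#'   applies); its `reduction` field lists, per eliminated species, the
#'   reconstruction expression and conserved total.
#' @export
reduce_by_conservation <- function(model) {
  specs <- model$species
  if (!length(model$reactions)) return(model)
  touched <- .boundary_touched(model)
  elig <- names(specs)[vapply(specs, function(sp) !(sp$name %in% touched), TRUE)]
  if (!length(elig)) return(model)

  # group by (compartment, D)
  key <- vapply(specs[elig], function(sp) paste(sp$compartment, sp$D), "")
  groups <- split(elig, key)
  elim <- list()

  for (grp in groups) {
    if (length(grp) < 2L) next
    # stoichiometry matrix: rows = group species, cols = ALL reactions
    S <- matrix(0, length(grp), length(model$reactions),
                dimnames = list(grp, names(model$reactions)))
    for (rn in names(model$reactions)) {
      st <- model$reactions[[rn]]$spec$stoich
      common <- intersect(names(st), grp)
      S[common, rn] <- st[common]
    }
    # left null space: y with t(y) %*% S = 0
    sv <- svd(S, nu = nrow(S))
    tolr <- max(dim(S)) * max(sv$d, 0) * .Machine$double.eps
    rank <- sum(sv$d > tolr)
    if (rank >= nrow(S)) next
    Y <- sv$u[, (rank + 1L):nrow(S), drop = FALSE]
    # Gauss-Jordan on the null-space basis: one pivot species per vector,
    # zero in every other vector, so each reconstruction expression only
    # references kept species
    pivots <- integer(0)
    for (k in seq_len(ncol(Y))) {
      cand <- setdiff(order(-abs(Y[, k])), pivots)
      cand <- cand[abs(Y[cand, k]) > 1e-10]
      if (!length(cand)) next
      piv <- cand[1]
      Y[, k] <- Y[, k] / Y[piv, k]
      for (j in seq_len(ncol(Y))) {
        if (j != k) Y[, j] <- Y[, j] - Y[piv, j] * Y[, k]
      }
      pivots <- c(pivots, piv)
      names(pivots)[length(pivots)] <- as.character(k)
    }
    for (k in seq_len(ncol(Y))) {
      kk <- match(as.character(k), names(pivots))
      if (is.na(kk)) next
      piv_idx <- pivots[kk]
      pivot <- grp[piv_idx]
      y <- Y[, k]
      # conserved combination must be spatially uniform initially
      comb <- numeric(length(model$initial[[pivot]]))
      for (idx in seq_along(grp)) {
        if (abs(y[idx]) < 1e-12) next
        comb <- comb + y[idx] * model$initial[[grp[idx]]]
      }
      if (diff(range(comb)) > 1e-9 * max(abs(comb), 1)) next
      total <- comb[1]
      others <- grp[abs(y) > 1e-12 & grp != pivot]
      coefs <- y[match(others, grp)]
      # pivot = total - sum(coef * other)
      lang <- if (length(others)) {
        acc <- NULL
        for (ii in seq_along(others)) {
          term <- if (abs(coefs[ii] - 1) < 1e-12) as.name(others[ii])
                  else call("*", coefs[ii], as.name(others[ii]))
          acc <- if (is.null(acc)) term else call("+", acc, term)
        }
        call("-", total, acc)
      } else total
      elim[[pivot]] <- list(species = pivot, total = total,
                            compartment = specs[[pivot]]$compartment,
                            coef = coefs, others = others, expr = lang)
    }
  }
  if (!length(elim)) return(model)

  # rebuild containers without the eliminated species, substituting rates
  sub_map <- lapply(elim, `[[`, "expr")
  names(sub_map) <- names(elim)
  keep <- setdiff(names(specs), names(elim))
  new_specs <- model$containers$species[keep]
  new_rxns <- model$containers$reactions
  for (rn in names(new_rxns)) {
    rx <- new_rxns[[rn]]
    e <- str2lang(rx$rate)
    e2 <- subst_lang(e, sub_map)
    rx$rate <- paste(deparse(e2), collapse = " ")
    st <- rx$stoich[setdiff(names(rx$stoich), names(elim))]
    if (!length(st)) { new_rxns[[rn]] <- NULL; next }
    rx$stoich <- st
    new_rxns[[rn]] <- rx
  }
  cont <- model$containers
  cont$species <- new_specs
  cont$reactions <- new_rxns
  reduced <- validate_model(cont, model$mesh, axisymmetric = model$axisymmetric)
  reduced$reduction <- elim
  reduced
}

#' Reconstruct eliminated species fields
#'
#' @param model a reduced `rd_model` (with a `reduction` record).
#' @param state global state vector of the reduced model.
#' @return named list of nodal fields for each eliminated species.
#' @export
reconstruct_eliminated <- function(model, state) {
  if (is.null(model$reduction)) return(list())
  dof <- model_dofmap(model)
  out <- list()
  for (el in model$reduction) {
    v <- rep(el$total, model$submeshes[[el$compartment]]$n_vertices)
    for (ii in seq_along(el$others)) {
      v <- v - el$coef[ii] * state[species_slice(dof, el$others[ii])]
    }
    out[[el$species]] <- v
  }
  out
}

#' Well-mixed (0D) reduction of a model
#'
#' Collapses every compartment to a single concentration: volume reactions
#' enter directly, surface-bound fluxes are scaled by
#' `surface measure / volume measure` on the volume side (with the
#' uM um s^-1 convention) and enter surface species directly.  Requires a
#' model without space-expression parameters (no well-mixed meaning).
#'
#' @param model an `rd_model`.
#' @return list with `rhs(t, y)` (named derivative vector), `y0` (named
#'   initial state: compartment averages), `measures` (per-compartment).
#' @export
reduce_to_ode <- function(model) {
  for (pm in model$parameters) {
    if (pm$kind == "space") {
      stop("model error: space-expression parameters have no well-mixed meaning",
           call. = FALSE)
    }
  }
  for (rx in model$reactions) {
    if (length(rx$rate$uses_coords)) {
      stop("model error: coordinate-dependent rates have no well-mixed meaning",
           call. = FALSE)
    }
  }
  meas <- lapply(model$submeshes, function(s) {
    if (is.null(model$weight)) sum(s$measures)
    else integrate_submesh(s, NULL, weight = model$weight[s$vertex_parent])
  })
  y0 <- vapply(names(model$species), function(nm) {
    sub <- model$submeshes[[model$species[[nm]]$compartment]]
    w <- if (is.null(model$weight)) NULL else model$weight[sub$vertex_parent]
    lm <- lumped_mass(sub, w)
    sum(lm * model$initial[[nm]]) / sum(lm)
  }, 1)
  sp_comp <- vapply(model$species, `[[`, "", "compartment")
  comp_kind <- vapply(model$compartments, `[[`, "", "kind")

  param_env <- function(t) {
    env <- list(t = t, pi = pi)
    for (pm in model$parameters) {
      env[[pm$name]] <- if (pm$kind %in% c("constant", "prestep")) pm$value
                        else eval(str2lang(pm$value), envir = env, enclos = baseenv())
    }
    env
  }

  rhs <- function(t, y) {
    names(y) <- names(model$species)
    env <- c(as.list(y), param_env(t))
    dy <- stats::setNames(numeric(length(y)), names(y))
    for (rx in model$reactions) {
      rate <- eval(rx$rate$expr, envir = env, enclos = baseenv())
      rate <- rate * rx$conv  # canonical: uM/s (volume) or molec um^-2 s^-1
      st <- rx$spec$stoich
      if (rx$spec$type == "volume") {
        for (nm in names(st)) dy[nm] <- dy[nm] + st[[nm]] * rate
      } else {
        surf <- rx$spec$compartment
        A <- meas[[surf]]
        for (nm in names(st)) {
          cp <- sp_comp[[nm]]
          if (comp_kind[[cp]] == "surface") {
            dy[nm] <- dy[nm] + st[[nm]] * rate
          } else {
            # molecules um^-2 s^-1 -> uM um s^-1 -> uM/s via A/V
            flux_um <- rate / MOLECULES_PER_UM3_PER_MICROMOLAR
            dy[nm] <- dy[nm] + st[[nm]] * flux_um * A / meas[[cp]]
          }
        }
      }
    }
    dy
  }
  list(rhs = rhs, y0 = y0, measures = meas)
}
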