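# Model validation: binding containers to a mesh.
#
# validate_model() checks every cross-reference (tags, adjacency, species
# membership per reaction type, units), parses all rate expressions with
# their exact species derivatives, evaluates initial conditions, and builds
# the dof map (species in insertion order, one contiguous block of its
# compartment's vertices each).  The result is the immutable input to the
# assembler and time stepper.

.eval_spatial <- function(value, coords) {
  nv <- nrow(coords)
  if (is.numeric(value)) return(rep(value, nv))
  e <- tryCatch(str2lang(value), error = function(err) {
    stop(sprintf("cannot parse spatial expression '%s'", value), call. = FALSE)
  })
  env <- list(x = coords[, 1],
              y = if (ncol(coords) >= 2) coords[, 2] else 0,
              z = if (ncol(coords) >= 3) coords[, 3] else 0,
              r = coords[, 1], pi = pi)
  v <- eval(e, envir = env, enclos = baseenv())
  if (length(v) == 1L) v <- rep(v, nv)
  if (any(!is.finite(v))) {
    stop(sprintf("spatial expression '%s' is non-finite on the compartment", value),
         call. = FALSE)
  }
  v
}

#' Validate containers against a mesh and build a model
#'
#' Performs all structural checks (compartment tags present at the right
#' dimension, surface adjacency consistent with the mesh, reaction species
#' membership per reaction type, rate units convertible to the canonical
#' unit of each type), parses every rate with exact species derivatives,
#' and evaluates initial conditions on compartment vertices.
#'
#' @param containers an `rd_containers` from [build_containers()].
#' @param mesh a `parent_mesh`.
#' @param axisymmetric if `TRUE`, the mesh is a 2D (r, z) half-section and
#'   all integrals are weighted by r (measures report `2*pi*int r`).
#' @return an object of class `rd_model`.
#' @export
validate_model <- function(containers, mesh, axisymmetric = FALSE) {
  stopifnot(inherits(containers, "rd_containers"), inherits(mesh, "parent_mesh"))
  comps <- containers$compartments
  specs <- containers$species
  pars <- containers$parameters
  rxns <- containers$reactions
  if (!length(comps)) stop("validation error: no compartments", call. = FALSE)
  if (!length(specs)) stop("validation error: no species", call. = FALSE)

  weight <- if (axisymmetric) axisymmetric_weight(mesh) else NULL

  # compartments: tags exist at the right dimension; surfaces border right
  submeshes <- list()
  adjacency <- list()
  for (cp in comps) {
    dimk <- if (cp$kind == "volume") "cell" else "facet"
    tags_avail <- if (dimk == "cell") mesh$cell_tags else mesh$facet_tags
    if (!any(tags_avail == cp$tag)) {
      stop(sprintf("validation error (tag): compartment '%s' tag %d absent from mesh %ss",
                   cp$name, cp$tag, dimk), call. = FALSE)
    }
    submeshes[[cp$name]] <- extract_submesh(mesh, cp$tag, dimk)
  }
  vol_names <- names(comps)[vapply(comps, function(c) c$kind == "volume", TRUE)]
  for (cp in comps) {
    if (cp$kind != "surface") next
    bad <- setdiff(cp$borders, vol_names)
    if (length(bad)) {
      stop(sprintf("validation error (adjacency): surface '%s' borders unknown volume '%s'",
                   cp$name, bad[1]), call. = FALSE)
    }
    adj <- surface_adjacency(mesh, cp$tag)
    declared_tags <- vapply(cp$borders, function(b) comps[[b]]$tag, 1L)
    if (length(declared_tags) != length(adj$volumes) ||
        !setequal(declared_tags, adj$volumes)) {
      stop(sprintf(paste("validation error (adjacency): surface '%s' declares bordering",
                         "tags {%s} but the mesh reports {%s}"),
                   cp$name, paste(declared_tags, collapse = ","),
                   paste(adj$volumes, collapse = ",")), call. = FALSE)
    }
    # reorder mesh adjacency sides to the declared border order
    if (length(adj$volumes) == 2L && adj$volumes[1] != declared_tags[1]) {
      adj$volumes <- rev(adj$volumes)
      adj$cells <- adj$cells[, 2:1, drop = FALSE]
      adj$normals <- adj$normals[2:1]
    }
    adjacency[[cp$name]] <- adj
  }

  # species: compartment exists, defaults, initial conditions
  init <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (is.null(comps[[sp$compartment]])) {
      stop(sprintf("validation error: species '%s' lives in unknown compartment '%s'",
                   sp$name, sp$compartment), call. = FALSE)
    }
    if (is.null(sp$unit)) {
      sp$unit <- if (comps[[sp$compartment]]$kind == "volume") "uM"
                 else "molecules/um^2"
      specs[[i]] <- sp
    }
    expect <- if (comps[[sp$compartment]]$kind == "volume") "uM" else "molecules/um^2"
    if (!units_compatible(sp$unit, expect)) {
      stop(sprintf("validation error (unit): species '%s' unit '%s' is not a %s concentration",
                   sp$name, sp$unit, comps[[sp$compartment]]$kind), call. = FALSE)
    }
    coords <- submesh_coords(submeshes[[sp$compartment]])
    v <- .eval_spatial(sp$initial, coords)
    init[[sp$name]] <- v * unit_conversion(sp$unit, expect)
  }

  # parameters: expression sanity
  par_names <- names(pars)
  for (pm in pars) {
    if (pm$kind == "time") {
      got <- .collect_symbols(str2lang(pm$value))
      bad <- setdiff(got$syms, c("t", "pi", par_names))
      if (length(bad)) {
        stop(sprintf("validation error: time parameter '%s' references unknown symbol '%s'",
                     pm$name, bad[1]), call. = FALSE)
      }
    } else if (pm$kind == "space") {
      got <- .collect_symbols(str2lang(pm$value))
      bad <- setdiff(got$syms, c(.rate_coords, "pi", par_names))
      if (length(bad)) {
        stop(sprintf("validation error: space parameter '%s' references unknown symbol '%s'",
                     pm$name, bad[1]), call. = FALSE)
      }
    }
  }

  # reactions: membership rules, unit conversion, parsed rates
  sp_comp <- vapply(specs, `[[`, "", "compartment")
  parsed <- list()
  for (rx in rxns) {
    bind <- comps[[rx$compartment]]
    if (is.null(bind)) {
      stop(sprintf("validation error: reaction '%s' bound to unknown compartment '%s'",
                   rx$name, rx$compartment), call. = FALSE)
    }
    if (rx$type == "volume" && bind$kind != "volume") {
      stop(sprintf("validation error: volume reaction '%s' must bind a volume compartment",
                   rx$name), call. = FALSE)
    }
    if (rx$type != "volume" && bind$kind != "surface") {
      stop(sprintf("validation error: reaction '%s' of type %s must bind a surface",
                   rx$name, rx$type), call. = FALSE)
    }
    if (rx$type == "volume_surface_volume" && length(bind$borders) != 2L) {
      stop(sprintf(paste("validation error (adjacency arity): reaction '%s' is",
                         "volume-surface-volume but surface '%s' borders only one volume"),
                   rx$name, rx$compartment), call. = FALSE)
    }
    allowed_comps <- switch(rx$type,
      volume = rx$compartment,
      surface = rx$compartment,
      volume_surface = c(rx$compartment, bind$borders),
      volume_surface_volume = c(rx$compartment, bind$borders))
    touch <- union(names(rx$stoich), character())
    pr <- tryCatch(
      parse_rate(rx$rate, species = names(specs), parameters = par_names),
      error = function(e) {
        stop(sprintf("reaction '%s': %s", rx$name, conditionMessage(e)),
             call. = FALSE)
      })
    touch <- union(touch, pr$species_used)
    bad <- setdiff(touch, names(specs))
    if (length(bad)) {
      stop(sprintf("validation error: reaction '%s' references undeclared species '%s'",
                   rx$name, bad[1]), call. = FALSE)
    }
    outside <- touch[!(sp_comp[touch] %in% allowed_comps)]
    if (length(outside)) {
      stop(sprintf(paste("validation error: reaction '%s' (%s) references species '%s'",
                         "of compartment '%s', outside its allowed compartments {%s}"),
                   rx$name, rx$type, outside[1], sp_comp[outside[1]],
                   paste(allowed_comps, collapse = ", ")), call. = FALSE)
    }
    if (rx$type == "volume_surface") {
      vols_used <- unique(sp_comp[touch][sp_comp[touch] %in% bind$borders])
      if (length(vols_used) > 1L) {
        stop(sprintf(paste("validation error: volume-surface reaction '%s' touches both",
                           "bordering volumes; declare it volume_surface_volume"),
                     rx$name), call. = FALSE)
      }
    }
    canonical <- .canonical_rate_unit(rx$type)
    if (!units_compatible(rx$rate_unit, canonical)) {
      stop(sprintf("validation error (unit): reaction '%s' rate unit '%s' is not convertible to %s",
                   rx$name, rx$rate_unit, canonical), call. = FALSE)
    }
    parsed[[rx$name]] <- list(
      spec = rx,
      rate = pr,
      conv = unit_conversion(rx$rate_unit, canonical))
  }

  structure(list(
    mesh = mesh,
    containers = containers,
    compartments = comps,
    species = specs,
    parameters = pars,
    reactions = parsed,
    submeshes = submeshes,
    adjacency = adjacency,
    initial = init,
    axisymmetric = axisymmetric,
    weight = weight,
    reduction = NULL
  ), class = "rd_model")
}

#' @export
print.rd_model <- function(x, ...) {
  cat(sprintf("<rd_model: %d compartments, %d species, %d parameters, %d reactions%s>\n",
              length(x$compartments), length(x$species), length(x$parameters),
              length(x$reactions),
              if (x$axisymmetric) ", axisymmetric" else ""))
  for (sp in x$species) {
    cat(sprintf("  species %-12s in %-12s D = %g\n", sp$name, sp$compartment, sp$D))
  }
  if (!is.null(x$reduction)) {
    cat(sprintf("  reduced: %s eliminated\n",
                paste(vapply(x$reduction, `[[`, "", "species"), collapse = ", ")))
  }
  invisible(x)
}

# dof map: species in insertion order, each a contiguous block of its
# compartment's local vertices
model_dofmap <- function(model) {
  offs <- integer(0)
  lens <- integer(0)
  off <- 0L
  for (sp in model$species) {
    n <- model$submeshes[[sp$compartment]]$n_vertices
    offs <- c(offs, off)
    lens <- c(lens, n)
    off <- off + n
  }
  names(offs) <- names(lens) <- names(model$species)
  list(offset = offs, length = lens, total = off)
}

# initial global state vector in canonical units (uM / molecules um^-2)
model_initial_state <- function(model) {
  dof <- model_dofmap(model)
  u <- numeric(dof$total)
  for (nm in names(model$species)) {
    u[dof$offset[[nm]] + seq_len(dof$length[[nm]])] <- model$initial[[nm]]
  }
  u
}

# slice a species block out of a global vector
species_slice <- function(dof, name) {
  dof$offset[[name]] + seq_len(dof$length[[name]])
}
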