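# Declarative model containers.
#
# A model is four ordered containers -- compartments, species, parameters,
# reactions -- later bound to a parent mesh by validate_model().  Insertion
# order is semantic: it fixes the global block/dof ordering, so containers
# are stored as ordered named lists and every rebuild from the same config
# yields identical orderings.

.canonical_rate_unit <- function(type) {
  switch(type,
         volume = "uM/s",
         surface = "molecules/um^2/s",
         volume_surface = "molecules/um^2/s",
         volume_surface_volume = "molecules/um^2/s",
         stop("unknown reaction type", call. = FALSE))
}

#' Declare a compartment
#'
#' @param name unique compartment name.
#' @param kind `"volume"` (dimension d) or `"surface"` (dimension d-1).
#' @param tag integer mesh tag of the compartment's cells/facets.
#' @param borders for surfaces: character vector (length 1 or 2) of the
#'   bordering volume compartment names, in the order defining the positive
#'   flux direction (outward from the first).
#' @export
compartment <- function(name, kind = c("volume", "surface"), tag,
                        borders = NULL) {
  kind <- match.arg(kind)
  if (is.list(borders)) borders <- unlist(borders)
  if (kind == "surface") {
    if (is.null(borders) || !length(borders) %in% 1:2) {
      stop(sprintf("surface compartment '%s' needs 1 or 2 bordering volumes", name),
           call. = FALSE)
    }
  } else if (!is.null(borders)) {
    stop(sprintf("volume compartment '%s' cannot declare borders", name),
         call. = FALSE)
  }
  structure(list(name = name, kind = kind, tag = as.integer(tag),
                 borders = borders), class = "rd_compartment")
}

#' Declare a species
#'
#' @param name unique species name (a valid symbol in rate expressions).
#' @param compartment name of the compartment the species lives in.
#' @param D diffusivity in um^2 s^-1 (volume) or surface diffusivity
#'   (um^2 s^-1 along the membrane); must be >= 0.
#' @param initial initial condition: a number, or an expression string in
#'   the spatial coordinates (`x`, `y`, `z`, `r`).
#' @param unit concentration unit; defaults to `"uM"` for volume species
#'   and `"molecules/um^2"` for surface species (set by validation when
#'   omitted).
#' @export
species <- function(name, compartment, D, initial = 0, unit = NULL) {
  if (!is.numeric(D) || length(D) != 1L || D < 0) {
    stop(sprintf("species '%s': D must be a single non-negative number", name),
         call. = FALSE)
  }
  if (make.names(name) != name) {
    stop(sprintf("species name '%s' is not a valid symbol", name), call. = FALSE)
  }
  structure(list(name = name, compartment = compartment, D = D,
                 initial = initial, unit = unit), class = "rd_species")
}

#' Declare a parameter
#'
#' @param name unique parameter name.
#' @param value a number (kind `"constant"` / `"prestep"`), or an expression
#'   string in `t` (kind `"time"`) or the spatial coordinates (kind
#'   `"space"`).
#' @param kind `"constant"`, `"time"` (time-expression), `"space"`
#'   (space-expression) or `"prestep"` (scalar updated before each step by
#'   a coupling rule or event).
#' @param unit declared unit string (bookkeeping; checked where the
#'   parameter fixes a rate's dimensions).
#' @export
parameter <- function(name, value, kind = c("constant", "time", "space", "prestep"),
                      unit = "1") {
  kind <- match.arg(kind)
  if (kind %in% c("constant", "prestep")) {
    if (!is.numeric(value) || length(value) != 1L) {
      stop(sprintf("parameter '%s' (%s) needs a single numeric value", name, kind),
           call. = FALSE)
    }
  } else if (!is.character(value)) {
    stop(sprintf("parameter '%s' (%s) needs an expression string", name, kind),
         call. = FALSE)
  }
  structure(list(name = name, kind = kind, value = value, unit = unit),
            class = "rd_parameter")
}

#' Declare a reaction
#'
#' @param name unique reaction name.
#' @param type `"volume"` (within one volume compartment), `"surface"`
#'   (among one surface's species), `"volume_surface"` (surface-bound, may
#'   reference traces from one bordering volume) or
#'   `"volume_surface_volume"` (traces from both bordering volumes of an
#'   interior interface).
#' @param compartment binding compartment: the volume for volume reactions,
#'   the surface otherwise.
#' @param rate rate expression string over species, parameters, `t` and
#'   coordinates.  Positive rate with positive stoichiometry produces the
#'   species; for surface-bound reactions, positive rate times positive
#'   stoichiometry is flux INTO the compartment of that species.
#' @param stoich named numeric vector of signed stoichiometries.
#' @param rate_unit unit of the rate expression; defaults to the canonical
#'   unit of the type (`uM/s` for volume, `molecules/um^2/s` otherwise;
#'   `uM*um/s` is accepted for surface-bound fluxes and converted).
#' @export
reaction <- function(name, type = c("volume", "surface", "volume_surface",
                                    "volume_surface_volume"),
                     compartment, rate, stoich, rate_unit = NULL) {
  type <- match.arg(type)
  if (is.list(stoich)) stoich <- unlist(stoich)
  if (is.null(names(stoich)) || any(names(stoich) == "")) {
    stop(sprintf("reaction '%s': stoich must be a named vector", name),
         call. = FALSE)
  }
  if (is.null(rate_unit)) rate_unit <- .canonical_rate_unit(type)
  structure(list(name = name, type = type, compartment = compartment,
                 rate = rate, stoich = stoich, rate_unit = rate_unit),
            class = "rd_reaction")
}

.named_container <- function(items, what) {
  nms <- vapply(items, `[[`, "", "name")
  dup <- nms[duplicated(nms)]
  if (length(dup)) {
    stop(sprintf("schema error at %s: duplicate name '%s'", what, dup[1]),
         call. = FALSE)
  }
  names(items) <- nms
  items
}

.required_keys <- list(
  compartments = c("name", "kind", "tag"),
  species = c("name", "compartment", "D"),
  parameters = c("name", "value"),
  reactions = c("name", "type", "compartment", "rate", "stoich"))

.known_keys <- list(
  compartments = c("name", "kind", "tag", "borders"),
  species = c("name", "compartment", "D", "initial", "unit"),
  parameters = c("name", "value", "kind", "unit"),
  reactions = c("name", "type", "compartment", "rate", "stoich", "rate_unit"))

#' Build the four model containers from a configuration document
#'
#' The configuration is a list with top-level arrays `compartments`,
#' `species`, `parameters` and `reactions` (each an array of records), as
#' produced by [read_model_config()] from YAML/JSON.  Optional blocks
#' (`solver`, `scalars`, `events`) are passed through untouched.  Insertion
#' order is preserved and determines the global dof ordering.
#'
#' @param config nested list configuration.
#' @return list of class `rd_containers` with elements `compartments`,
#'   `species`, `parameters`, `reactions`, `extra`.
#' @export
build_containers <- function(config) {
  if (!is.list(config)) stop("schema error: config must be a list", call. = FALSE)
  need <- c("compartments", "species")
  for (k in need) {
    if (is.null(config[[k]])) {
      stop(sprintf("schema error at $%s: section missing", k), call. = FALSE)
    }
  }
  check_rec <- function(rec, section, i) {
    miss <- setdiff(.required_keys[[section]], names(rec))
    if (length(miss)) {
      stop(sprintf("schema error at $%s[%d]: missing required field '%s'",
                   section, i, miss[1]), call. = FALSE)
    }
    unk <- setdiff(names(rec), .known_keys[[section]])
    if (length(unk)) {
      stop(sprintf("schema error at $%s[%d]: unknown key '%s'",
                   section, i, unk[1]), call. = FALSE)
    }
  }
  mk <- function(section, ctor) {
    recs <- config[[section]]
    if (is.null(recs)) return(structure(list(), names = character()))
    out <- vector("list", length(recs))
    for (i in seq_along(recs)) {
      check_rec(recs[[i]], section, i)
      out[[i]] <- do.call(ctor, recs[[i]])
    }
    .named_container(out, section)
  }
  comps <- mk("compartments", compartment)
  specs <- mk("species", species)
  pars <- mk("parameters", parameter)
  rxns <- mk("reactions", reaction)
  structure(list(compartments = comps, species = specs, parameters = pars,
                 reactions = rxns,
                 extra = config[setdiff(names(config),
                                        c("compartments", "species",
                                          "parameters", "reactions"))]),
            class = "rd_containers")
}

#' Read a model configuration file (YAML or JSON)
#' @param path file path; `.json` is parsed as JSON, anything else as YAML.
#' @return nested list suitable for [build_containers()].
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Write containers back to a configuration file (round trip)
#' @param containers an `rd_containers` (or `rd_model`, whose containers
#'   are used).
#' @param path output path; `.json` writes JSON, anything else YAML.
#' @export
write_model_config <- function(containers, path) {
  if (inherits(containers, "rd_model")) containers <- containers$containers
  strip <- function(items) {
    lapply(unname(items), function(it) {
      rec <- unclass(it)
      rec <- rec[!vapply(rec, is.null, TRUE)]
      if (!is.null(rec$stoich)) rec$stoich <- as.list(rec$stoich)
      rec
    })
  }
  doc <- c(list(compartments = strip(containers$compartments),
                species = strip(containers$species),
                parameters = strip(containers$parameters),
                reactions = strip(containers$reactions)),
           containers$extra)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}
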