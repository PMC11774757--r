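# Post-processing: derived quantities and file output.

#' Compartment average of a species field
#'
#' `(1' M u) / measure` with the consistent (weighted, for axisymmetric
#' runs) mass matrix, i.e. the exact mean of the P1 interpolant.
#'
#' @param series a `solution_series`, or an `rd_model` together with a
#'   nodal vector via `state`.
#' @param species species name.
#' @param state nodal values of that species (defaults to the final stored
#'   field when `series` is a `solution_series`).
#' @param time pick the stored output at this time (default: last).
#' @return scalar average in the species' native unit.
#' @export
compartment_average <- function(series, species, state = NULL, time = NULL) {
  if (inherits(series, "solution_series")) {
    sys <- series$system
    model <- series$model
    if (is.null(state)) {
      k <- if (is.null(time)) length(series$times)
           else which.min(abs(series$times - time))
      state <- series$fields[[k]][[species]]
    }
  } else {
    model <- series
    sys <- build_system(model)
    if (is.null(state)) stop("state required when passing a model", call. = FALSE)
  }
  cn <- model$species[[species]]$compartment
  lm <- sys$comp_lump[[cn]]
  sum(lm * state) / sum(lm)
}

#' Total amount of species in molecules
#'
#' Volume species: `uM -> molecules um^-3` times the compartment volume
#' integral; surface species: `molecules um^-2` times the surface integral.
#' Axisymmetric models integrate with the r weight and scale by `2*pi`.
#'
#' @param series a `solution_series`.
#' @param species character vector of species names (default: all).
#' @param time stored output time to use (default: last).
#' @return total molecule count (numeric scalar).
#' @export
total_amount <- function(series, species = NULL, time = NULL) {
  stopifnot(inherits(series, "solution_series"))
  model <- series$model
  sys <- series$system
  if (is.null(species)) species <- names(model$species)
  k <- if (is.null(time)) length(series$times)
       else which.min(abs(series$times - time))
  axis_scale <- if (model$axisymmetric) 2 * pi else 1
  total <- 0
  for (nm in species) {
    cn <- model$species[[nm]]$compartment
    kind <- model$compartments[[cn]]$kind
    lm <- sys$comp_lump[[cn]]
    amt <- sum(lm * series$fields[[k]][[nm]])
    if (kind == "volume") amt <- amt * MOLECULES_PER_UM3_PER_MICROMOLAR
    total <- total + amt * axis_scale
  }
  total
}

#' Time series of averages and totals
#'
#' One row per stored output: time, per-species compartment averages
#' (native units) and per-species totals (molecules), plus any coupled
#' scalars.
#'
#' @param series a `solution_series`.
#' @return data frame.
#' @export
timeseries_table <- function(series) {
  model <- series$model
  sys <- series$system
  axis_scale <- if (model$axisymmetric) 2 * pi else 1
  rows <- lapply(seq_along(series$times), function(k) {
    row <- list(time = series$times[k])
    for (nm in names(model$species)) {
      cn <- model$species[[nm]]$compartment
      lm <- sys$comp_lump[[cn]]
      v <- series$fields[[k]][[nm]]
      row[[paste0("avg_", nm)]] <- sum(lm * v) / sum(lm)
      amt <- sum(lm * v) * axis_scale
      if (model$compartments[[cn]]$kind == "volume") {
        amt <- amt * MOLECULES_PER_UM3_PER_MICROMOLAR
      }
      row[[paste0("total_", nm)]] <- amt
    }
    for (sn in names(series$scalars[[k]])) {
      row[[sn]] <- series$scalars[[k]][[sn]]
    }
    as.data.frame(row)
  })
  do.call(rbind, rows)
}

#' Write simulation outputs to a directory
#'
#' Emits one legacy-VTK field snapshot per stored output time, a CSV
#' time-series table (17 significant digits), and a JSON run manifest with
#' a configuration hash and solver settings.  Byte-identical across
#' repeated runs of the same configuration.
#'
#' @param series a `solution_series`.
#' @param directory output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the manifest list.
#' @export
write_outputs <- function(series, directory, prefix = "run") {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) {
      stop(sprintf("cannot create output directory '%s'", directory), call. = FALSE)
    }
  }
  model <- series$model
  mesh <- model$mesh
  nv <- nrow(mesh$vertices)
  for (k in seq_along(series$times)) {
    pd <- list()
    for (nm in names(model$species)) {
      sub <- model$submeshes[[model$species[[nm]]$compartment]]
      full <- rep(NA_real_, nv)
      full[sub$vertex_parent] <- series$fields[[k]][[nm]]
      pd[[nm]] <- full
    }
    write_vtk(mesh, file.path(directory, sprintf("%s_%04d.vtk", prefix, k - 1L)),
              point_data = pd)
  }
  ts <- timeseries_table(series)
  csv_path <- file.path(directory, paste0(prefix, "_timeseries.csv"))
  # fixed 17-significant-digit formatting for reproducibility diffs
  fmt <- as.data.frame(lapply(ts, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else col
  }))
  utils::write.csv(fmt, csv_path, row.names = FALSE, quote = FALSE)

  cfg_file <- tempfile(fileext = ".yml")
  write_model_config(model$containers, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  manifest <- list(
    package = "rdmix",
    package_version = as.character(utils::packageVersion("rdmix")),
    config_hash = cfg_hash,
    solver_settings = series$system$settings,
    n_outputs = length(series$times),
    t_final = max(series$times),
    n_steps = nrow(series$log))
  jsonlite::write_json(manifest,
                       file.path(directory, paste0(prefix, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  step_log <- file.path(directory, paste0(prefix, "_steps.csv"))
  fmtlog <- as.data.frame(lapply(series$log, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else col
  }))
  utils::write.csv(fmtlog, step_log, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Export a sparse operator in MatrixMarket format (debugging aid)
#' @param mat a sparse Matrix.
#' @param path output `.mtx` path.
#' @export
write_operator <- function(mat, path) {
  Matrix::writeMM(methods::as(mat, "CsparseMatrix"), path)
  invisible(path)
}
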