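# Unit algebra over the base system (um, s, molecule).
#
# Volume concentrations are carried in uM, surface concentrations in
# molecules um^-2.  The fixed bridge between the two is
#   1 uM = 602.214076 molecules um^-3
# (Avogadro's number scaled to litre -> um^3), so boundary fluxes can be
# expressed either as uM um s^-1 (volume side) or molecules um^-2 s^-1
# (surface side) and converted exactly.

#' Molecules per cubic micrometre in a one-micromolar solution
#'
#' The fixed conversion constant between volume concentration (uM) and
#' number density (molecules um^-3): 1 uM = 602.214076 molecules um^-3.
#' @export
MOLECULES_PER_UM3_PER_MICROMOLAR <- 602.214076

.unit_atoms <- function() {
  # scale = value of one unit in base units; dim = powers of (um, s, molecule)
  list(
    um        = list(scale = 1,                 dim = c(1, 0, 0)),
    s         = list(scale = 1,                 dim = c(0, 1, 0)),
    molecule  = list(scale = 1,                 dim = c(0, 0, 1)),
    molecules = list(scale = 1,                 dim = c(0, 0, 1)),
    uM        = list(scale = 602.214076,        dim = c(-3, 0, 1)),
    mM        = list(scale = 602214.076,        dim = c(-3, 0, 1)),
    nm        = list(scale = 1e-3,              dim = c(1, 0, 0)),
    ms        = list(scale = 1e-3,              dim = c(0, 1, 0)),
    min       = list(scale = 60,                dim = c(0, 1, 0)),
    dimensionless = list(scale = 1,             dim = c(0, 0, 0))
  )
}

#' Parse a unit string
#'
#' Understands products, quotients and integer powers of the atoms
#' `um`, `s`, `molecule(s)`, `uM`, `mM`, `nm`, `ms`, `min`,
#' `dimensionless` (or `1`), e.g. `"uM/s"`, `"molecules/um^2/s"`,
#' `"uM*um/s"`, `"um^2/s"`.
#'
#' @param text unit string.
#' @return an object of class `rd_unit` with fields `scale` (value of one
#'   such unit in base um/s/molecule units) and `dim` (powers of um, s,
#'   molecule).
#' @export
parse_unit <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  atoms <- .unit_atoms()
  s <- gsub(" ", "", text)
  if (s == "" || s == "1") {
    return(structure(list(scale = 1, dim = c(0, 0, 0), text = text),
                     class = "rd_unit"))
  }
  # tokenize on * and /, keeping the operator that precedes each factor
  parts <- strsplit(s, "(?=[*/])", perl = TRUE)[[1]]
  scale <- 1
  dim <- c(0, 0, 0)
  sign <- 1
  for (p in parts) {
    if (p == "") next
    if (p %in% c("*", "/")) {
      sign <- if (p == "/") -1 else 1
      next
    }
    op <- substr(p, 1, 1)
    if (op == "*" || op == "/") {
      sign <- if (op == "/") -1 else 1
      p <- substr(p, 2, nchar(p))
    }
    m <- regmatches(p, regexec("^([A-Za-z]+|1)(\\^(-?[0-9]+))?$", p))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("cannot parse unit factor '%s' in '%s'", p, text),
           call. = FALSE)
    }
    name <- m[2]
    pw <- if (m[4] == "") 1L else as.integer(m[4])
    pw <- sign * pw
    if (name == "1") next
    a <- atoms[[name]]
    if (is.null(a)) {
      stop(sprintf("unknown unit '%s' in '%s'", name, text), call. = FALSE)
    }
    scale <- scale * a$scale^pw
    dim <- dim + a$dim * pw
    sign <- 1
  }
  structure(list(scale = scale, dim = dim, text = text), class = "rd_unit")
}

#' @export
print.rd_unit <- function(x, ...) {
  cat(sprintf("<unit '%s': scale %g, dim um^%g s^%g molecule^%g>\n",
              x$text, x$scale, x$dim[1], x$dim[2], x$dim[3]))
  invisible(x)
}

#' Conversion factor between two units
#'
#' @param from,to unit strings or `rd_unit` objects.
#' @return scalar `k` such that a quantity `x from == (k*x) to`.
#' @export
unit_conversion <- function(from, to) {
  if (is.character(from)) from <- parse_unit(from)
  if (is.character(to)) to <- parse_unit(to)
  if (!isTRUE(all(abs(from$dim - to$dim) < 1e-12))) {
    stop(sprintf("units '%s' and '%s' are not dimensionally compatible",
                 from$text, to$text), call. = FALSE)
  }
  from$scale / to$scale
}

units_compatible <- function(from, to) {
  if (is.character(from)) from <- parse_unit(from)
  if (is.character(to)) to <- parse_unit(to)
  isTRUE(all(abs(from$dim - to$dim) < 1e-12))
}
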