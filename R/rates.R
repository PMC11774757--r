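# Symbolic rate expressions.
#
# Rates are strings in a fixed grammar: arithmetic over declared species,
# parameters, time `t` and spatial coordinates `x`, `y`, `z`, `r`, using a
# whitelisted function set.  They are parsed to R language objects, checked
# against the symbol table, and differentiated exactly with respect to every
# species symbol so that the Newton Jacobian is exact by construction.
# Smooth macros (tanh, hill, softmin) are rewritten into primitives that
# stats::D differentiates; hard conditionals on species are rejected so that
# discontinuous behaviour goes through the event system instead.

.rate_functions <- c("+", "-", "*", "/", "^", "(", "exp", "log", "sqrt",
                     "tanh", "hill", "softmin", "pow")

.rate_coords <- c("x", "y", "z", "r")

# rewrite macros into D()-differentiable primitives
.rewrite_macros <- function(e) {
  if (is.call(e)) {
    fn <- as.character(e[[1]])
    args <- lapply(as.list(e)[-1], .rewrite_macros)
    if (fn == "pow") {
      return(call("^", args[[1]], args[[2]]))
    }
    if (fn == "tanh") {
      a <- args[[1]]
      # tanh(a) = 1 - 2/(exp(2a)+1)
      return(call("-", 1, call("/", 2, call("+", call("exp", call("*", 2, a)), 1))))
    }
    if (fn == "hill") {
      # hill(c, K, n) = c^n / (K^n + c^n)
      if (length(args) != 3L) stop("hill() takes (conc, K, n)", call. = FALSE)
      cn <- call("^", args[[1]], args[[3]])
      return(call("/", cn, call("+", call("^", args[[2]], args[[3]]), cn)))
    }
    if (fn == "softmin") {
      # softmin(a, b, k) = -log(exp(-k a) + exp(-k b)) / k, smooth minimum
      if (length(args) != 3L) stop("softmin() takes (a, b, k)", call. = FALSE)
      k <- args[[3]]
      ea <- call("exp", call("*", call("-", k), args[[1]]))
      eb <- call("exp", call("*", call("-", k), args[[2]]))
      return(call("/", call("-", call("log", call("+", ea, eb))), k))
    }
    return(as.call(c(e[[1]], args)))
  }
  e
}

.collect_symbols <- function(e, syms = character(), funs = character()) {
  if (is.name(e)) {
    return(list(syms = union(syms, as.character(e)), funs = funs))
  }
  if (is.call(e)) {
    fn <- e[[1]]
    if (!is.name(fn)) {
      stop("only simple function calls are allowed in rate expressions",
           call. = FALSE)
    }
    funs <- union(funs, as.character(fn))
    for (a in as.list(e)[-1]) {
      got <- .collect_symbols(a, syms, funs)
      syms <- got$syms
      funs <- got$funs
    }
    return(list(syms = syms, funs = funs))
  }
  if (is.numeric(e) || is.integer(e)) {
    return(list(syms = syms, funs = funs))
  }
  stop(sprintf("disallowed construct in rate expression: %s",
               deparse(e)), call. = FALSE)
}

#' Parse a rate expression into a differentiable form
#'
#' Parses the string, verifies every symbol is declared and every function is
#' whitelisted (`+ - * / ^ pow exp log sqrt tanh hill softmin`), and computes
#' the exact partial derivative with respect to each requested species symbol.
#'
#' @param text rate expression string, e.g. `"kf*A*B"` or
#'   `"Vmax*C/(Km + C)"`.
#' @param species character vector of species symbols the expression may
#'   depend on (derivatives are produced for each that actually occurs).
#' @param parameters character vector of parameter symbols in scope.
#' @return an object of class `rd_rate`: list with `expr` (R expression),
#'   `deriv` (named list of derivative expressions, one per referenced
#'   species), `species_used`, `params_used`, `uses_coords`, `uses_time`.
#' @examples
#' r <- parse_rate("kf*A*B", species = c("A", "B"), parameters = "kf")
#' r$deriv$A   # kf * B
#' @export
parse_rate <- function(text, species = character(), parameters = character()) {
  stopifnot(is.character(text), length(text) == 1L)
  e <- tryCatch(str2lang(text),
                error = function(err) {
                  stop(sprintf("cannot parse rate expression '%s': %s",
                               text, conditionMessage(err)), call. = FALSE)
                })
  got <- .collect_symbols(e)
  bad_fun <- setdiff(got$funs, .rate_functions)
  if (length(bad_fun)) {
    if (any(bad_fun %in% c("ifelse", "if", "max", "min", "abs", "sign"))) {
      stop(sprintf(paste("non-smooth construct '%s' is not allowed in rates;",
                         "express discontinuous behaviour as an event"),
                   bad_fun[1]), call. = FALSE)
    }
    stop(sprintf("unknown function '%s' in rate expression '%s'",
                 bad_fun[1], text), call. = FALSE)
  }
  allowed <- c(species, parameters, "t", .rate_coords, "pi")
  bad_sym <- setdiff(got$syms, allowed)
  if (length(bad_sym)) {
    stop(sprintf("unknown symbol '%s' in rate expression '%s'",
                 bad_sym[1], text), call. = FALSE)
  }
  e2 <- .rewrite_macros(e)
  sp_used <- intersect(species, got$syms)
  derivs <- lapply(sp_used, function(s) stats::D(e2, s))
  names(derivs) <- sp_used
  structure(list(
    text = text,
    expr = e2,
    deriv = derivs,
    species_used = sp_used,
    params_used = intersect(parameters, got$syms),
    uses_coords = intersect(.rate_coords, got$syms),
    uses_time = "t" %in% got$syms
  ), class = "rd_rate")
}

#' @export
print.rd_rate <- function(x, ...) {
  cat(sprintf("<rate '%s'; depends on species: %s>\n", x$text,
              if (length(x$species_used)) paste(x$species_used, collapse = ", ")
              else "(none)"))
  invisible(x)
}

# evaluate a rate (or derivative) expression over vectorized environments
eval_rate <- function(expr, env_list) {
  v <- eval(expr, envir = env_list, enclos = baseenv())
  if (any(!is.finite(v))) {
    stop("rate expression evaluated to a non-finite value", call. = FALSE)
  }
  v
}

# substitute symbols in a language object (used by conservation reduction)
subst_lang <- function(e, map) {
  eval(call("substitute", e, map))
}
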