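#' @title Fuzzy sets and linguistic variables
#' @description Trapezoidal fuzzy sets (triangular when b = c), linguistic
#'   variables over closed universes, and loss-free JSON serialisation of a
#'   variable definition.
#' @name fuzzy_sets
NULL

#' Construct a trapezoidal fuzzy set
#'
#' @param name linguistic label.
#' @param a,b,c,d breakpoints with `a <= b <= c <= d`; `b == c` gives a
#'   triangular set, `a == b` or `c == d` a crisp edge.
#' @return object of class `fiska_fuzzy_set`.
#' @export
fuzzy_set <- function(name, a, b, c, d) {
  if (!(a <= b && b <= c && c <= d)) {
    stop_config("fuzzy set '%s': breakpoints must satisfy a <= b <= c <= d", name)
  }
  structure(list(name = as.character(name), a = a, b = b, c = c, d = d),
            class = "fiska_fuzzy_set")
}

#' Trapezoidal membership degree
#'
#' Piecewise-linear membership: 0 outside `[a, d]`, a rising ramp on
#' `[a, b]`, 1 on the plateau `[b, c]`, a falling ramp on `[c, d]`. At a
#' degenerate edge (`a == b` or `c == d`) the plateau value 1 applies at the
#' shared point, so crisp sets are representable.
#'
#' @param x numeric vector of crisp values.
#' @param set a `fiska_fuzzy_set`.
#' @return membership degrees in \[0, 1\], same length as `x`.
#' @examples
#' s <- fuzzy_set("demo", 0, 20, 40, 60)
#' trapezoid_membership(c(10, 30, 70), s)  # 0.5 1.0 0.0
#' @export
trapezoid_membership <- function(x, set) {
  mu <- numeric(length(x))
  mu[x >= set$b & x <= set$c] <- 1
  if (set$b > set$a) {
    i <- x >= set$a & x < set$b
    mu[i] <- (x[i] - set$a) / (set$b - set$a)
  }
  if (set$d > set$c) {
    i <- x > set$c & x <= set$d
    mu[i] <- (set$d - x[i]) / (set$d - set$c)
  }
  mu
}

#' Construct a linguistic variable
#'
#' @param name variable name.
#' @param universe closed interval `c(lo, hi)`, `lo < hi`.
#' @param sets list of `fiska_fuzzy_set`s with unique names whose supports
#'   lie inside the universe.
#' @return object of class `fiska_variable`.
#' @export
linguistic_variable <- function(name, universe, sets) {
  if (length(universe) != 2 || universe[1] >= universe[2]) {
    stop_config("variable '%s': universe must be [lo, hi] with lo < hi", name)
  }
  nm <- vapply(sets, function(s) s$name, "")
  if (anyDuplicated(nm)) stop_config("variable '%s': duplicate set names", name)
  for (s in sets) {
    if (s$a < universe[1] - 1e-9 || s$d > universe[2] + 1e-9) {
      stop_config("variable '%s': set '%s' support outside universe", name, s$name)
    }
  }
  structure(list(name = as.character(name), universe = as.numeric(universe),
                 sets = sets),
            class = "fiska_variable")
}

set_names <- function(variable) vapply(variable$sets, function(s) s$name, "")

#' Fuzzify a crisp value
#'
#' Evaluates every set of the variable at `value`. Values outside the
#' universe are clamped to the nearest edge (an extreme PRA or age must rank,
#' not crash); clamping is reported via a condition of class
#' `fiska_clamp` so callers can log it.
#'
#' @param value crisp input (scalar or vector).
#' @param variable a `fiska_variable`.
#' @return for scalar input, a named vector of membership degrees (one per
#'   set); for vector input, a matrix with one row per value.
#' @export
fuzzify <- function(value, variable) {
  lo <- variable$universe[1]; hi <- variable$universe[2]
  if (any(value < lo | value > hi)) {
    signalCondition(structure(
      class = c("fiska_clamp", "condition"),
      list(message = sprintf(
        "fiska: clamped %d value(s) of '%s' to universe [%g, %g]",
        sum(value < lo | value > hi), variable$name, lo, hi), call = NULL)))
    value <- pmin(pmax(value, lo), hi)
  }
  m <- vapply(variable$sets, function(s) trapezoid_membership(value, s),
              numeric(length(value)))
  if (length(value) == 1) {
    m <- as.numeric(m)
    names(m) <- set_names(variable)
    m
  } else {
    colnames(m) <- set_names(variable)
    m
  }
}

var_to_list <- function(v) {
  list(name = v$name, universe = v$universe,
       sets = lapply(v$sets, function(s) s[c("name", "a", "b", "c", "d")]))
}

var_from_list <- function(x) {
  linguistic_variable(
    x$name, unlist(x$universe),
    lapply(x$sets, function(s) fuzzy_set(s$name, s$a, s$b, s$c, s$d)))
}

#' Default linguistic-variable definition
#'
#' Loads the packaged eight-input / one-output variable definition (or a
#' user file in the same JSON schema). The default input set counts are
#' 2, 4, 3, 3, 6, 4, 4, 2, whose full Cartesian rule grid is 13,824.
#'
#' @param path JSON variable definition; `NULL` loads the packaged default.
#' @return list with elements `inputs` (named list of `fiska_variable`) and
#'   `output` (a `fiska_variable` with five sets).
#' @export
load_variables <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "variables_default.json", package = "fiska")
  }
  if (!file.exists(path)) stop_config("variable definition not found: %s", path)
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  inputs <- lapply(x$inputs, var_from_list)
  names(inputs) <- vapply(inputs, function(v) v$name, "")
  output <- var_from_list(x$output)
  if (length(output$sets) != 5) {
    stop_config("output variable must have exactly 5 sets, got %d", length(output$sets))
  }
  list(inputs = inputs, output = output)
}

#' Write a variable definition to JSON
#' @param variables list as returned by [load_variables()].
#' @param path output file.
#' @export
write_variables <- function(variables, path) {
  jsonlite::write_json(
    list(inputs = lapply(unname(variables$inputs), var_to_list),
         output = var_to_list(variables$output)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
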