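#' @title Mamdani inference engine
#' @description Rule firing by the min T-norm, max aggregation of clipped
#'   consequents, and centre-of-gravity defuzzification on a sampled output
#'   universe — the classical max-min Mamdani MISO pipeline.
#' @name fuzzy_infer
NULL

#' Construct a fuzzy if-then rule
#'
#' @param antecedent named character vector / list mapping input-variable
#'   names to set names; variables absent from the mapping are
#'   unconstrained. May be empty (an always-firing rule).
#' @param consequent output set name.
#' @param n optional provenance weight (e.g. supporting leaf size from rule
#'   induction); kept through serialisation.
#' @return object of class `fiska_rule`.
#' @export
fuzzy_rule <- function(antecedent, consequent, n = NA_real_) {
  antecedent <- as.list(antecedent)
  if (length(antecedent) > 0 && is.null(names(antecedent))) {
    stop_config("rule antecedent must be named by input variable")
  }
  structure(list(antecedent = lapply(antecedent, as.character),
                 consequent = as.character(consequent), n = as.numeric(n)),
            class = "fiska_rule")
}

#' Construct and validate a rule base
#'
#' @param rules list of `fiska_rule`.
#' @param inputs named list of input `fiska_variable`s.
#' @param output output `fiska_variable` with exactly five sets
#'   (very_low ... very_high).
#' @return object of class `fiska_rulebase`.
#' @export
rule_base <- function(rules, inputs, output) {
  if (length(rules) < 1) stop_config("rule base must contain at least one rule")
  if (length(output$sets) != 5) stop_config("output variable must have exactly 5 sets")
  out_names <- set_names(output)
  for (r in rules) {
    for (v in names(r$antecedent)) {
      if (!v %in% names(inputs)) {
        stop_config("rule references unknown input variable '%s'", v)
      }
      if (!r$antecedent[[v]] %in% set_names(inputs[[v]])) {
        stop_config("rule references unknown set '%s' of variable '%s'",
                    r$antecedent[[v]], v)
      }
    }
    if (!r$consequent %in% out_names) {
      stop_config("rule references unknown output set '%s'", r$consequent)
    }
  }
  structure(list(rules = rules, inputs = inputs, output = output),
            class = "fiska_rulebase")
}

#' @export
print.fiska_rulebase <- function(x, ...) {
  cat(sprintf("Fuzzy rule base: %d rule(s), %d input variable(s)\n",
              length(x$rules), length(x$inputs)))
  show <- utils::head(x$rules, 10)
  for (r in show) {
    ant <- if (length(r$antecedent) == 0) "TRUE" else
      paste(sprintf("%s IS %s", names(r$antecedent), unlist(r$antecedent)),
            collapse = " AND ")
    cat("  IF", ant, "THEN priority IS", r$consequent, "\n")
  }
  if (length(x$rules) > 10) cat("  ...", length(x$rules) - 10, "more\n")
  invisible(x)
}

#' Firing strength of a rule (min T-norm)
#'
#' @param rule a `fiska_rule`.
#' @param fuzzified named list: per input variable, the named degree vector
#'   from [fuzzify()].
#' @return degree in \[0, 1\]; an empty antecedent fires at 1.
#' @export
firing_strength <- function(rule, fuzzified) {
  if (length(rule$antecedent) == 0) return(1)
  degs <- vapply(names(rule$antecedent), function(v) {
    if (is.null(fuzzified[[v]])) {
      stop_input("no fuzzified degrees supplied for variable '%s'", v)
    }
    d <- unname(fuzzified[[v]][rule$antecedent[[v]]])
    if (length(d) != 1 || is.na(d)) {
      stop_config("unknown set '%s' for variable '%s'", rule$antecedent[[v]], v)
    }
    d
  }, 0)
  min(degs)
}

output_grid <- function(output, resolution) {
  if (resolution <= 0) stop_config("resolution must be > 0")
  seq(output$universe[1], output$universe[2], by = resolution)
}

# membership of every output set sampled on the grid: sets x grid matrix
output_set_matrix <- function(output, grid) {
  t(vapply(output$sets, function(s) trapezoid_membership(grid, s),
           numeric(length(grid))))
}

#' Aggregate clipped rule consequents (max T-conorm)
#'
#' At each sample point of the output universe, takes the max over rules of
#' min(firing strength, consequent-set membership).
#'
#' @param rulebase a `fiska_rulebase`.
#' @param strengths numeric vector of firing strengths, one per rule.
#' @param resolution sample step on the output universe (default 0.1).
#' @return list with `grid` (sample points) and `mu` (aggregated degrees).
#' @export
aggregate_rules <- function(rulebase, strengths, resolution = 0.1) {
  if (length(strengths) != length(rulebase$rules)) {
    stop_input("strengths must align with rules (%d vs %d)",
               length(strengths), length(rulebase$rules))
  }
  grid <- output_grid(rulebase$output, resolution)
  M <- output_set_matrix(rulebase$output, grid)
  out_names <- set_names(rulebase$output)
  cons <- vapply(rulebase$rules, function(r) r$consequent, "")
  # max clip level per output set, then max over the 5 clipped sets
  clip <- vapply(out_names, function(s) {
    idx <- cons == s
    if (any(idx)) max(strengths[idx]) else 0
  }, 0)
  mu <- numeric(length(grid))
  for (k in seq_along(out_names)) {
    if (clip[k] > 0) mu <- pmax(mu, pmin(clip[k], M[k, ]))
  }
  list(grid = grid, mu = mu)
}

#' Centre-of-gravity defuzzification
#'
#' Discrete rectangle-rule approximation of
#' `COG = integral(mu(y) y dy) / integral(mu(y) dy)` over the sampled output
#' universe.
#'
#' @param mu sampled aggregated membership.
#' @param grid matching sample points.
#' @return crisp value inside the support of `mu`.
#' @export
defuzzify_cog <- function(mu, grid) {
  total <- sum(mu)
  if (total <= 0) {
    stop_domain("no rule fired: aggregated membership is identically zero")
  }
  sum(mu * grid) / total
}

#' Run the full Mamdani inference for one input vector
#'
#' fuzzify -> min firing -> max aggregation -> COG. Deterministic for fixed
#' inputs, rule base and resolution.
#'
#' @param inputs named numeric vector/list of crisp values, one per input
#'   variable referenced by the rules (out-of-universe values clamp).
#' @param rulebase a `fiska_rulebase`.
#' @param resolution output sample step (default 0.1).
#' @return crisp priority score on the output universe.
#' @export
infer <- function(inputs, rulebase, resolution = 0.1) {
  fuzzified <- lapply(rulebase$inputs, function(v) {
    if (is.null(inputs[[v$name]])) {
      stop_input("missing crisp input for variable '%s'", v$name)
    }
    fuzzify(inputs[[v$name]], v)
  })
  strengths <- vapply(rulebase$rules, firing_strength, 0, fuzzified = fuzzified)
  agg <- aggregate_rules(rulebase, strengths, resolution)
  tryCatch(defuzzify_cog(agg$mu, agg$grid),
           fiska_domain_error = function(e) {
             stop_domain("no rule fired for inputs (%s)",
                         paste(sprintf("%s=%g", names(inputs), unlist(inputs)),
                               collapse = ", "))
           })
}

# Batch inference over a data.frame of crisp inputs (one column per input
# variable). Same semantics as infer(), vectorised for cohort-scale use.
infer_batch <- function(data, rulebase, resolution = 0.1) {
  n <- nrow(data)
  out_names <- set_names(rulebase$output)
  # per-variable membership matrices: rows x sets
  fz <- lapply(rulebase$inputs, function(v) {
    if (is.null(data[[v$name]])) {
      stop_input("missing input column '%s'", v$name)
    }
    m <- fuzzify(as.numeric(data[[v$name]]), v)
    if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(m)))
    m
  })
  # firing strength matrix: rows x rules
  S <- matrix(1, nrow = n, ncol = length(rulebase$rules))
  for (j in seq_along(rulebase$rules)) {
    r <- rulebase$rules[[j]]
    for (v in names(r$antecedent)) {
      S[, j] <- pmin(S[, j], fz[[v]][, r$antecedent[[v]]])
    }
  }
  cons <- vapply(rulebase$rules, function(r) r$consequent, "")
  clip <- vapply(out_names, function(s) {
    idx <- cons == s
    if (any(idx)) apply(S[, idx, drop = FALSE], 1, max) else numeric(n)
  }, numeric(n))
  if (is.null(dim(clip))) clip <- matrix(clip, nrow = 1, dimnames = list(NULL, out_names))
  grid <- output_grid(rulebase$output, resolution)
  M <- output_set_matrix(rulebase$output, grid)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    mu <- numeric(length(grid))
    for (k in seq_along(out_names)) {
      if (clip[i, k] > 0) mu <- pmax(mu, pmin(clip[i, k], M[k, ]))
    }
    if (sum(mu) <= 0) {
      scores[i] <- NA_real_
    } else {
      scores[i] <- sum(mu * grid) / sum(mu)
    }
  }
  scores
}

#' Size of the full Cartesian rule grid
#'
#' The number of rules a complete enumeration of one set per variable would
#' need — the combinatorial load the tree-based rule extraction avoids. The
#' default eight-variable definition gives 2 x 4 x 3 x 3 x 6 x 4 x 4 x 2 =
#' 13,824.
#'
#' @param inputs list of input `fiska_variable`s.
#' @return integer product of per-variable set counts.
#' @export
rule_grid_size <- function(inputs) {
  if (length(inputs) < 1) stop_input("need at least one variable")
  prod(vapply(inputs, function(v) length(v$sets), 0))
}

#' Map a crisp priority score to its maximal-membership output class
#'
#' @param score crisp value(s) on the output universe.
#' @param output the output `fiska_variable`.
#' @return ordered factor over the five priority classes.
#' @export
score_to_class <- function(score, output) {
  ok <- !is.na(score)
  m <- vapply(output$sets,
              function(s) trapezoid_membership(score[ok], s),
              numeric(sum(ok)))
  if (is.null(dim(m))) m <- matrix(m, nrow = sum(ok))
  idx <- rep(NA_integer_, length(score))
  if (any(ok)) idx[ok] <- apply(m, 1, which.max)
  factor(set_names(output)[idx], levels = set_names(output), ordered = TRUE)
}

#' Write a rule base to JSON
#'
#' The JSON document carries the input variables, the output variable and
#' the rules; [read_rulebase()] restores it loss-free.
#'
#' @param rulebase a `fiska_rulebase`.
#' @param path output file.
#' @export
write_rulebase <- function(rulebase, path) {
  doc <- list(
    inputs = lapply(unname(rulebase$inputs), var_to_list),
    output = var_to_list(rulebase$output),
    rules = lapply(rulebase$rules, function(r) {
      x <- list(antecedent = r$antecedent, consequent = r$consequent)
      if (!is.na(r$n)) x$n <- r$n
      x
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a rule base from JSON
#' @param path file written by [write_rulebase()] (or hand-authored in the
#'   same schema).
#' @return a validated `fiska_rulebase`.
#' @export
read_rulebase <- function(path) {
  if (!file.exists(path)) stop_config("rule-base file not found: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  inputs <- lapply(doc$inputs, var_from_list)
  names(inputs) <- vapply(inputs, function(v) v$name, "")
  output <- var_from_list(doc$output)
  rules <- lapply(doc$rules, function(r) {
    fuzzy_rule(r$antecedent, r$consequent, n = if (is.null(r$n)) NA_real_ else r$n)
  })
  rule_base(rules, inputs, output)
}
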