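#' @title Rule induction from score-labelled cohorts
#' @description Builds the training table (crisp predictors + point score +
#'   quantised priority class), induces a classification tree, translates
#'   root-to-leaf paths into fuzzy rules by maximal-overlap set matching,
#'   and evaluates the tree with stratified k-fold cross-validation.
#' @name rule_induction
NULL

PREDICTOR_VARS <- c("medical_urgency", "pra", "recipient_age", "waiting_time",
                    "hla_mismatch", "abo", "age_difference", "predicted_survival")

#' Build a score-labelled training table
#'
#' Pairs each patient with their assigned donor, computes the eight crisp
#' predictors, the total point score, and the quantised priority class used
#' as the tree's response. ABO-incompatible pairings are rejected with a
#' message (they can never be allocated, so they carry no label).
#'
#' @param patients validated waiting list.
#' @param donors data.frame of validated donor records.
#' @param assignment character vector of donor ids, one per patient row.
#' @param weights a `fiska_weights` table.
#' @param thresholds optional explicit class cut points for
#'   [quantize_priority()]; `NULL` uses quintiles of the table's scores.
#' @return a `fiska_training_table`: patient/donor ids, the eight
#'   predictors, `score` and `priority`, with a `predictors` attribute.
#' @export
build_training_table <- function(patients, donors, assignment, weights,
                                 thresholds = NULL) {
  if (length(assignment) != nrow(patients)) {
    stop_input("assignment must name one donor per patient")
  }
  if (!all(assignment %in% donors$donor_id)) {
    stop_input("assignment references unknown donor id(s)")
  }
  parts <- lapply(unique(assignment), function(did) {
    rows <- patients[assignment == did, , drop = FALSE]
    donor <- donors[donors$donor_id == did, , drop = FALSE]
    inp <- allocation_inputs(rows, donor)
    inp$donor_id <- did
    inp
  })
  tab <- do.call(rbind, parts)
  # restore the original patient order so the table is deterministic
  tab <- tab[match(patients$patient_id, tab$patient_id), , drop = FALSE]
  bad <- tab$abo_label == "incompatible"
  if (any(bad)) {
    message(sprintf("dropping %d ABO-incompatible pairing(s): %s", sum(bad),
                    paste(utils::head(tab$patient_id[bad], 5), collapse = ", ")))
    tab <- tab[!bad, , drop = FALSE]
  }
  tab$score <- score_from_inputs(tab, weights)
  tab$priority <- quantize_priority(tab$score, thresholds)
  rownames(tab) <- NULL
  out <- tab[, c("patient_id", "donor_id", PREDICTOR_VARS, "score", "priority")]
  attr(out, "predictors") <- PREDICTOR_VARS
  attr(out, "thresholds") <- attr(tab$priority, "thresholds")
  class(out) <- c("fiska_training_table", class(out))
  out
}

# overlap of a fuzzy set with an interval [L, U]: integral of membership
# (trapezoid quadrature on a fine grid; exact enough for set selection)
set_interval_overlap <- function(set, L, U) {
  if (U <= L) return(trapezoid_membership(L, set))
  g <- seq(L, U, length.out = 201)
  mu <- trapezoid_membership(g, set)
  sum((mu[-1] + mu[-length(mu)]) / 2) * (U - L) / (length(g) - 1)
}

plateau_center <- function(set) (set$b + set$c) / 2

# pick the fuzzy set of `variable` best matching the path interval (lo, hi]:
# maximal overlap integral; ties by plateau-centre distance to the interval
# midpoint, then by lower set order.
match_set <- function(variable, lo, hi) {
  ulo <- variable$universe[1]; uhi <- variable$universe[2]
  L <- max(lo, ulo); U <- min(hi, uhi)
  if (L > U) {
    # interval lies outside the universe: use the nearest edge point
    L <- U <- if (lo > uhi) uhi else ulo
  }
  ov <- vapply(variable$sets, set_interval_overlap, 0, L = L, U = U)
  tol <- max(ov) * 1e-9 + 1e-12
  cand <- which(ov >= max(ov) - tol)
  if (length(cand) > 1 || max(ov) <= 0) {
    if (max(ov) <= 0) cand <- seq_along(variable$sets)
    mid <- (L + U) / 2
    dist <- vapply(variable$sets[cand], function(s) abs(plateau_center(s) - mid), 0)
    cand <- cand[which(dist <= min(dist) + 1e-12)]
  }
  set_names(variable)[min(cand)]
}

#' Translate a classification tree into a fuzzy rule base
#'
#' Each leaf becomes one rule: the threshold constraints along its
#' root-to-leaf path are intersected into one interval per constrained
#' variable, and the fuzzy set with maximal membership integral over that
#' interval becomes the antecedent term (ties broken by plateau-centre
#' distance to the interval midpoint, then set order). Unconstrained
#' variables are omitted. The leaf's majority class is the consequent.
#' Duplicate rules merge; contradictory duplicates (same antecedent,
#' different consequent) keep the rule from the more populous leaf and
#' report the conflict as a message.
#'
#' @param tree a `fiska_tree`.
#' @param variables variable definition from [load_variables()] (the
#'   output variable supplies the five consequent sets).
#' @return a `fiska_rulebase`.
#' @export
tree_to_fuzzy_rules <- function(tree, variables) {
  inputs <- variables$inputs
  for (v in tree$predictors) {
    if (!v %in% names(inputs)) {
      stop_config("split variable '%s' has no linguistic-variable definition", v)
    }
  }
  rules <- list()
  walk <- function(node, lo, hi) {
    if (node$type == "leaf") {
      ant <- list()
      for (v in names(lo)) {
        if (is.finite(lo[[v]]) || is.finite(hi[[v]])) {
          if (lo[[v]] >= hi[[v]]) {
            stop_domain("malformed tree: empty interval for '%s'", v)
          }
          ant[[v]] <- match_set(inputs[[v]], lo[[v]], hi[[v]])
        }
      }
      rules[[length(rules) + 1]] <<- fuzzy_rule(ant, node$class, n = node$n)
      return(invisible())
    }
    l <- lo; h <- hi
    h[[node$var]] <- min(h[[node$var]], node$threshold)
    walk(node$left, lo, h)
    l[[node$var]] <- max(l[[node$var]], node$threshold)
    walk(node$right, l, hi)
  }
  lo0 <- stats::setNames(as.list(rep(-Inf, length(tree$predictors))), tree$predictors)
  hi0 <- stats::setNames(as.list(rep(Inf, length(tree$predictors))), tree$predictors)
  walk(tree$root, lo0, hi0)

  # merge duplicates / resolve contradictions by leaf support
  key_of <- function(r) {
    if (length(r$antecedent) == 0) return("<always>")
    v <- sort(names(r$antecedent))
    paste(v, unlist(r$antecedent[v]), sep = "=", collapse = "&")
  }
  keep <- list()
  for (r in rules) {
    k <- key_of(r)
    if (is.null(keep[[k]])) {
      keep[[k]] <- r
    } else if (keep[[k]]$consequent == r$consequent) {
      keep[[k]]$n <- keep[[k]]$n + r$n
    } else {
      message(sprintf(
        "conflicting rules for antecedent [%s]: keeping '%s' (n=%g) over '%s' (n=%g)",
        k,
        if (keep[[k]]$n >= r$n) keep[[k]]$consequent else r$consequent,
        max(keep[[k]]$n, r$n),
        if (keep[[k]]$n >= r$n) r$consequent else keep[[k]]$consequent,
        min(keep[[k]]$n, r$n)))
      if (r$n > keep[[k]]$n) keep[[k]] <- r
    }
  }
  rule_base(unname(keep), inputs, variables$output)
}

fold_assignment <- function(y, k, seed) {
  folds <- integer(length(y))
  set.seed(seed)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Stratified k-fold cross-validation of the classification tree
#'
#' Splits the table into `k` stratified folds (seeded shuffle within each
#' class), fits a tree on each training portion and scores the held-out
#' fold. Per class, one-vs-rest sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP) and precision TP/(TP+FP) are averaged over the folds in which
#' they are defined; overall accuracy is averaged over folds. All metrics
#' are reported in percent.
#'
#' @param table a `fiska_training_table`.
#' @param k number of folds (>= 2); default 10.
#' @param max_depth,min_leaf tree parameters, see [fit_tree()].
#' @param seed fold-shuffle seed; default 42.
#' @return object of class `fiska_cv_report`: `per_class` (3 x 5 matrix of
#'   percentages), `accuracy` (percent), `k`, `seed`.
#' @export
cross_validate <- function(table, k = 10, max_depth = 6, min_leaf = 20,
                           seed = 42) {
  if (k < 2) stop_config("k must be >= 2")
  if (nrow(table) < k) stop_config("table has fewer rows than folds")
  y <- factor(table$priority, levels = PRIORITY_LEVELS, ordered = TRUE)
  counts <- tabulate(as.integer(y), length(PRIORITY_LEVELS))
  absent <- PRIORITY_LEVELS[counts == 0]
  if (length(absent) > 0) {
    warning("class(es) absent from the table: ", paste(absent, collapse = ", "),
            "; their metrics are undefined")
  }
  folds <- fold_assignment(y, k, seed)
  sens <- spec <- prec <- matrix(NA_real_, nrow = k, ncol = 5,
                                 dimnames = list(NULL, PRIORITY_LEVELS))
  acc <- numeric(k)
  for (f in seq_len(k)) {
    train <- table[folds != f, , drop = FALSE]
    attr(train, "predictors") <- attr(table, "predictors")
    test <- table[folds == f, , drop = FALSE]
    fit <- suppressWarnings(fit_tree(train, max_depth = max_depth,
                                     min_leaf = min_leaf))
    pred <- predict(fit, test)
    truth <- factor(test$priority, levels = PRIORITY_LEVELS)
    acc[f] <- 100 * mean(pred == truth)
    for (ci in seq_along(PRIORITY_LEVELS)) {
      cl <- PRIORITY_LEVELS[ci]
      tp <- sum(pred == cl & truth == cl)
      fn <- sum(pred != cl & truth == cl)
      fp <- sum(pred == cl & truth != cl)
      tn <- sum(pred != cl & truth != cl)
      if (tp + fn > 0) sens[f, ci] <- 100 * tp / (tp + fn)
      if (tn + fp > 0) spec[f, ci] <- 100 * tn / (tn + fp)
      if (tp + fp > 0) prec[f, ci] <- 100 * tp / (tp + fp)
    }
  }
  per_class <- rbind(
    sensitivity = colMeans(sens, na.rm = TRUE),
    specificity = colMeans(spec, na.rm = TRUE),
    precision = colMeans(prec, na.rm = TRUE))
  per_class[is.nan(per_class)] <- NA_real_
  structure(list(per_class = per_class, accuracy = mean(acc), k = k, seed = seed),
            class = "fiska_cv_report")
}

#' @export
print.fiska_cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated performance (percent)\n", x$k))
  print(round(x$per_class, 1))
  cat(sprintf("Overall accuracy: %.1f\n", x$accuracy))
  invisible(x)
}

#' @export
as.data.frame.fiska_cv_report <- function(x, ...) {
  df <- as.data.frame(t(x$per_class))
  df <- cbind(priority = rownames(df), df)
  rownames(df) <- NULL
  df$overall_accuracy <- x$accuracy
  df
}
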