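#' @title Deterministic classification tree
#' @description A small Gini CART used for rule induction: axis-aligned
#'   binary splits on numeric predictors, depth and leaf-size constraints,
#'   fully deterministic tie-breaking (first predictor in column order,
#'   lowest threshold). Binary categorical predictors (urgency, ABO) enter
#'   as 0/1 indicators, for which a threshold split and a category-subset
#'   split coincide.
#' @name tree
NULL

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# Best split of rows `idx` over predictors X (matrix), labels y (integer).
# Returns NULL or list(var, threshold, impurity).
best_split <- function(X, y, idx, K, min_leaf) {
  n <- length(idx)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    xs <- X[idx, j]
    o <- order(xs, method = "radix")
    xo <- xs[o]
    yo <- y[idx][o]
    # cumulative class counts at each cut position
    cum <- vapply(seq_len(K), function(k) cumsum(yo == k), numeric(n))
    pos <- seq_len(n - 1)
    valid <- pos >= min_leaf & (n - pos) >= min_leaf & xo[pos] < xo[pos + 1]
    if (!any(valid)) next
    pos <- pos[valid]
    nl <- pos
    nr <- n - pos
    left <- cum[pos, , drop = FALSE]
    right <- rep(cum[n, ], each = length(pos)) - left
    gl <- 1 - rowSums((left / nl)^2)
    gr <- 1 - rowSums((right / nr)^2)
    w <- (nl * gl + nr * gr) / n
    i <- which.min(w)  # ties -> lowest threshold
    if (is.null(best) || w[i] < best$impurity - 1e-12) {
      best <- list(var = j, threshold = (xo[pos[i]] + xo[pos[i] + 1]) / 2,
                   impurity = w[i])
    }
  }
  best
}

#' Fit a classification tree to a labelled training table
#'
#' Grows a binary Gini-impurity tree over the table's predictors with the
#' `priority` column as response. Splits send `x <= threshold` left. Growth
#' stops at `max_depth`, when a node is pure, when a child would fall under
#' `min_leaf` rows, or when no split reduces impurity. A single-class table
#' yields a degenerate one-leaf tree with a warning.
#'
#' @param table a `fiska_training_table` (or data.frame with a `predictors`
#'   attribute and a `priority` factor column).
#' @param max_depth maximum tree depth (root = depth 0); default 6.
#' @param min_leaf minimum rows per leaf; default 20.
#' @return object of class `fiska_tree`.
#' @export
fit_tree <- function(table, max_depth = 6, min_leaf = 20) {
  if (max_depth < 1 || min_leaf < 1) stop_config("tree parameters must be positive")
  predictors <- attr(table, "predictors")
  if (is.null(predictors)) {
    predictors <- setdiff(names(table), c("patient_id", "donor_id", "score",
                                          "priority", "abo_label"))
  }
  if (!"priority" %in% names(table)) stop_input("training table lacks a priority column")
  y <- as.integer(factor(table$priority, levels = PRIORITY_LEVELS))
  if (anyNA(y)) stop_input("priority labels outside the five classes")
  X <- as.matrix(as.data.frame(lapply(table[predictors], as.numeric)))
  K <- length(PRIORITY_LEVELS)
  if (length(unique(y)) < 2) {
    warning("single-class training table: degenerate one-leaf tree")
  }

  grow <- function(idx, depth) {
    counts <- tabulate(y[idx], K)
    leaf <- list(type = "leaf",
                 class = PRIORITY_LEVELS[which.max(counts)],
                 counts = counts, n = length(idx))
    if (depth >= max_depth || length(idx) < 2 * min_leaf ||
        max(counts) == length(idx)) {
      return(leaf)
    }
    sp <- best_split(X, y, idx, K, min_leaf)
    if (is.null(sp) || gini_impurity(counts) - sp$impurity <= 1e-10) return(leaf)
    go_left <- X[idx, sp$var] <= sp$threshold
    list(type = "split", var = predictors[sp$var], threshold = sp$threshold,
         n = length(idx),
         left = grow(idx[go_left], depth + 1),
         right = grow(idx[!go_left], depth + 1))
  }

  structure(list(root = grow(seq_along(y), 0), predictors = predictors,
                 levels = PRIORITY_LEVELS,
                 params = list(max_depth = max_depth, min_leaf = min_leaf)),
            class = "fiska_tree")
}

#' Predict classes from a fitted tree
#' @param object a `fiska_tree`.
#' @param newdata data.frame containing the tree's predictor columns.
#' @param ... unused.
#' @return ordered factor of predicted priority classes.
#' @export
predict.fiska_tree <- function(object, newdata, ...) {
  n <- nrow(newdata)
  out <- character(n)
  descend <- function(node, idx) {
    if (length(idx) == 0) return(invisible())
    if (node$type == "leaf") {
      out[idx] <<- node$class
      return(invisible())
    }
    go_left <- as.numeric(newdata[[node$var]][idx]) <= node$threshold
    descend(node$left, idx[go_left])
    descend(node$right, idx[!go_left])
  }
  descend(object$root, seq_len(n))
  factor(out, levels = object$levels, ordered = TRUE)
}

count_leaves <- function(node) {
  if (node$type == "leaf") 1L else count_leaves(node$left) + count_leaves(node$right)
}

#' Number of leaves of a fitted tree
#' @param tree a `fiska_tree`.
#' @export
n_leaves <- function(tree) count_leaves(tree$root)

#' @export
print.fiska_tree <- function(x, ...) {
  cat(sprintf("Classification tree: %d leaves (max_depth %d, min_leaf %d)\n",
              n_leaves(x), x$params$max_depth, x$params$min_leaf))
  invisible(x)
}
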