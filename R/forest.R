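# Bagged CART random forest for object classification: Gini-impurity splits,
# bootstrap resampling, majority vote with fixed tie-breaks.

#' Random-forest configuration
#'
#' Defaults are the grid-search-optimized values used for the tailings-site
#' classification: 75 trees, maximum depth 16, 0.1 of the features considered
#' per split (floor of one), minimum 3 samples to split a node.
#'
#' @param n_estimators Number of trees K (>= 1).
#' @param max_depth Maximum tree depth (root = depth 0; >= 1).
#' @param max_features Fraction of features drawn at each split, in (0, 1];
#'   the number used is `ceiling(max_features * n_features)`, at least 1.
#' @param min_samples_split Minimum node size to attempt a split (>= 2).
#' @param seed Master seed; tree i uses the derived stream `seed + i`.
#' @return Object of class `forest_config`.
#' @export
forest_config <- function(n_estimators = 75, max_depth = 16,
                          max_features = 0.1, min_samples_split = 3,
                          seed = 1L) {
  if (n_estimators < 1) stop("n_estimators must be >= 1")
  if (max_depth < 1) stop("max_depth must be >= 1")
  if (max_features <= 0 || max_features > 1) {
    stop("max_features must be in (0, 1]")
  }
  if (min_samples_split < 2) stop("min_samples_split must be >= 2")
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 max_features = max_features,
                 min_samples_split = as.integer(min_samples_split),
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Gini impurity of a node
#'
#' `1 - sum(p_j^2)` over the class proportions of the node: 0 for a pure node,
#' 0.5 for a 50/50 two-class node, 0.75 for four equal classes.
#'
#' @param counts Nonnegative class counts with positive total.
#' @return Scalar impurity in \[0, 1).
#' @export
gini <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  total <- sum(counts)
  if (total <= 0) stop("empty node: total count must be positive")
  1 - sum((counts / total)^2)
}

#' Sample-weighted impurity of a candidate split
#'
#' `sum(n_i / n * gini(i))` over child nodes; an empty child contributes 0
#' with weight 0. The training split chosen at a node minimizes this.
#'
#' @param children List of class-count vectors, one per child.
#' @return Scalar weighted impurity.
#' @export
split_gini <- function(children) {
  n <- sum(vapply(children, sum, numeric(1)))
  if (n <= 0) stop("empty split")
  s <- 0
  for (cc in children) {
    ni <- sum(cc)
    if (ni > 0) s <- s + ni / n * gini(cc)
  }
  s
}

# Best threshold on one feature by exhaustive scan of midpoints between
# consecutive sorted unique values. Returns c(score, threshold) or NULL.
best_split_feature <- function(x, yi, nclass) {
  o <- order(x)
  xs <- x[o]; ys <- yi[o]
  n <- length(xs)
  cum <- vapply(seq_len(nclass), function(k) cumsum(ys == k), numeric(n))
  cum <- matrix(cum, nrow = n)
  cuts <- which(xs[-n] < xs[-1])  # split after position i
  if (!length(cuts)) return(NULL)
  nl <- cuts
  nr <- n - nl
  left <- cum[cuts, , drop = FALSE]
  right <- matrix(cum[n, ], nrow = length(cuts), ncol = nclass,
                  byrow = TRUE) - left
  gl <- 1 - rowSums((left / nl)^2)
  gr <- 1 - rowSums((right / nr)^2)
  score <- (nl * gl + nr * gr) / n
  j <- which.min(score)
  c(score[j], (xs[cuts[j]] + xs[cuts[j] + 1]) / 2)
}

grow_tree <- function(x, yi, cfg, nclass, mtry) {
  nfeat <- ncol(x)
  nodes <- list()
  new_node <- function() {
    nodes[[length(nodes) + 1]] <<- list()
    length(nodes)
  }
  build <- function(rows, depth) {
    id <- new_node()
    counts <- tabulate(yi[rows], nbins = nclass)
    leaf_class <- which.max(counts)  # ties: first class in canonical order
    if (depth >= cfg$max_depth || length(rows) < cfg$min_samples_split ||
        gini(counts) == 0) {
      nodes[[id]] <<- list(leaf = TRUE, class = leaf_class)
      return(id)
    }
    feats <- sort(sample.int(nfeat, mtry))
    best <- NULL
    for (f in feats) {
      sp <- best_split_feature(x[rows, f], yi[rows], nclass)
      # ties: lowest feature index (scan order), then lowest threshold
      if (!is.null(sp) && (is.null(best) || sp[1] < best$score)) {
        best <- list(score = sp[1], feature = f, threshold = sp[2])
      }
    }
    if (is.null(best)) {
      nodes[[id]] <<- list(leaf = TRUE, class = leaf_class)
      return(id)
    }
    go_left <- x[rows, best$feature] <= best$threshold
    left <- build(rows[go_left], depth + 1)
    right <- build(rows[!go_left], depth + 1)
    nodes[[id]] <<- list(leaf = FALSE, feature = best$feature,
                         threshold = best$threshold, left = left,
                         right = right)
    id
  }
  build(seq_len(nrow(x)), 0L)
  nodes
}

#' Train a bagged CART random forest
#'
#' Grows `n_estimators` binary CART trees, each on a bootstrap sample of the
#' training rows (n draws with replacement), splitting recursively on the
#' Gini-minimizing threshold over a random subset of
#' `ceiling(max_features * n_features)` features per node, and stopping at
#' `max_depth`, `min_samples_split`, or purity. Deterministic given the
#' configuration seed (tree i draws from stream `seed + i`).
#'
#' @param features Data frame or numeric matrix of features (no missing
#'   values).
#' @param labels Class labels (factor or character); at least 2 classes.
#' @param cfg A [forest_config()].
#' @return Object of class `fvc_forest`.
#' @export
train_forest <- function(features, labels, cfg = forest_config()) {
  stopifnot(inherits(cfg, "forest_config"))
  x <- as.matrix(features)
  if (!is.numeric(x)) stop("features must be numeric")
  if (anyNA(x)) stop("features must not contain missing values")
  if (is.factor(labels)) labels <- as.character(labels)
  n <- nrow(x)
  if (n < cfg$min_samples_split) {
    stop("need at least min_samples_split labeled rows")
  }
  if (length(labels) != n) stop("labels must match feature rows")
  classes <- if (all(labels %in% fvc_classes())) {
    intersect(fvc_classes(), unique(labels))
  } else sort(unique(labels))
  if (length(classes) < 2) {
    stop("single-class training set: a forest needs at least 2 classes")
  }
  yi <- match(labels, classes)
  mtry <- max(1L, as.integer(ceiling(cfg$max_features * ncol(x))))
  trees <- vector("list", cfg$n_estimators)
  boot <- vector("list", cfg$n_estimators)
  for (i in seq_len(cfg$n_estimators)) {
    set.seed(cfg$seed + i)
    idx <- sample.int(n, n, replace = TRUE)
    trees[[i]] <- grow_tree(x[idx, , drop = FALSE], yi[idx], cfg,
                            length(classes), mtry)
    boot[[i]] <- idx
  }
  structure(list(trees = trees, bootstrap = boot, classes = classes,
                 feature_names = colnames(x), config = cfg, mtry = mtry),
            class = "fvc_forest")
}

#' @export
print.fvc_forest <- function(x, ...) {
  cat(sprintf("<fvc_forest> %d trees, %d classes (%s), mtry %d\n",
              length(x$trees), length(x$classes),
              paste(x$classes, collapse = ", "), x$mtry))
  invisible(x)
}

predict_tree <- function(nodes, x) {
  n <- nrow(x)
  out <- integer(n)
  node <- rep(1L, n)
  active <- seq_len(n)
  while (length(active)) {
    done <- logical(length(active))
    for (j in seq_along(active)) {
      i <- active[j]
      nd <- nodes[[node[i]]]
      if (nd$leaf) {
        out[i] <- nd$class
        done[j] <- TRUE
      } else {
        node[i] <- if (x[i, nd$feature] <= nd$threshold) nd$left else nd$right
      }
    }
    active <- active[!done]
  }
  out
}

#' Predict classes (or votes) from a trained forest
#'
#' Each tree votes for one class per row; the prediction is the class with the
#' most votes, ties broken by the first class in canonical order. Votes per
#' row always sum to the number of trees.
#'
#' @param object An `fvc_forest`.
#' @param newdata Feature data frame/matrix with the training columns.
#' @param type `"class"` (default) for labels, `"votes"` for the vote matrix.
#' @param ... Unused.
#' @return Character vector of class labels, or an integer vote matrix with
#'   one column per class.
#' @export
predict.fvc_forest <- function(object, newdata, type = c("class", "votes"),
                               ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (!is.null(object$feature_names)) {
    if (is.null(colnames(x))) {
      if (ncol(x) != length(object$feature_names)) {
        stop("feature columns do not match the training features")
      }
    } else {
      if (!all(object$feature_names %in% colnames(x))) {
        stop("feature columns do not match the training features: missing ",
             paste(setdiff(object$feature_names, colnames(x)), collapse = ", "))
      }
      x <- x[, object$feature_names, drop = FALSE]
    }
  }
  if (anyNA(x)) stop("features must not contain missing values")
  nclass <- length(object$classes)
  votes <- matrix(0L, nrow(x), nclass,
                  dimnames = list(NULL, object$classes))
  for (tr in object$trees) {
    p <- predict_tree(tr, x)
    votes[cbind(seq_len(nrow(x)), p)] <- votes[cbind(seq_len(nrow(x)), p)] + 1L
  }
  if (type == "votes") return(votes)
  object$classes[max.col(votes, ties.method = "first")]
}
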