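#' Fit the regression forest
#'
#' Fits `M` CART regression trees with per-node random feature subsetting
#' (via \pkg{ranger}, single-threaded so a fixed seed gives identical trees).
#' The fitted trees are frozen: the meta-learned head never changes them.
#'
#' @param x N x d numeric feature matrix (N >= 2, finite).
#' @param y length-N numeric yield vector (percent scale).
#' @param config a [forest_config()].
#' @return an object of class `yield_forest`.
#' @export
fit_forest <- function(x, y, config = forest_config()) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 training reactions")
  if (ncol(x) == 0) stop("feature matrix has no columns")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite input")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  mtry <- config$max_features %||% max(1L, floor(ncol(x) / 3))
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = config$n_trees,
    mtry = min(mtry, ncol(x)),
    min.node.size = config$min_leaf,
    replace = config$bootstrap,
    sample.fraction = 1,
    max.depth = config$max_depth %||% 0L,
    seed = config$seed,
    num.threads = 1,
    oob.error = FALSE)
  structure(list(rf = fit, config = config, feature_dim = ncol(x),
                 feature_names = colnames(x)),
            class = "yield_forest")
}

#' @export
print.yield_forest <- function(x, ...) {
  cat("yield_forest:", x$config$n_trees, "trees on", x$feature_dim,
      "features\n")
  invisible(x)
}

#' Per-tree prediction matrix
#'
#' Evaluates every tree on every row: entry (i, m) is tree m's prediction for
#' reaction i. Row i is the tree-output vector `x_i'` consumed by the
#' attention head; its uniform row mean is the classic random-forest
#' prediction.
#'
#' @param forest a `yield_forest` (or a `yield_forest_dump` from
#'   [deserialize_forest()]).
#' @param features N x d matrix with `d == forest$feature_dim`.
#' @return N x M numeric matrix (rows named after `features` rows).
#' @export
tree_transform <- function(forest, features) UseMethod("tree_transform")

#' @export
tree_transform.yield_forest <- function(forest, features) {
  features <- as.matrix(features)
  if (ncol(features) != forest$feature_dim)
    stop("feature dimension mismatch: got ", ncol(features), ", expected ",
         forest$feature_dim)
  colnames(features) <- forest$feature_names
  p <- predict(forest$rf, data = features, predict.all = TRUE,
               num.threads = 1)$predictions
  p <- matrix(p, nrow = nrow(features))
  rownames(p) <- rownames(features)
  p
}

#' Ensemble-mean forest prediction (the baseline predictor)
#'
#' Defined as the uniform average over the columns of [tree_transform()], so
#' the plain random-forest baseline is exactly the unweighted special case of
#' the attention-combined model.
#'
#' @inheritParams tree_transform
#' @return numeric prediction vector.
#' @export
forest_predict <- function(forest, features) {
  rowMeans(tree_transform(forest, features))
}

#' Serialize / restore a fitted forest
#'
#' Dumps every tree (split feature, threshold, children, leaf value) to a
#' versioned JSON file, so a meta-trained model can be reloaded and evaluated
#' without refitting. `deserialize_forest()` returns a `yield_forest_dump`
#' whose [tree_transform()] walks the dumped trees directly (values smaller
#' than or equal to the threshold go left).
#'
#' @param forest a `yield_forest`.
#' @param path output file; `NULL` returns the JSON string.
#' @return `serialize_forest()` the path (or JSON string) invisibly;
#'   `deserialize_forest()` a `yield_forest_dump`.
#' @export
serialize_forest <- function(forest, path = NULL) {
  trees <- lapply(seq_len(forest$config$n_trees), function(m) {
    ti <- ranger::treeInfo(forest$rf, m)
    list(left = ti$leftChild, right = ti$rightChild,
         splitvar = ti$splitvarID, splitval = ti$splitval,
         prediction = ti$prediction)
  })
  obj <- list(format = "metayield_forest", version = 1L,
              n_trees = forest$config$n_trees,
              feature_names = forest$feature_names, trees = trees)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}

#' @rdname serialize_forest
#' @param path_or_json path to, or string of, a forest JSON dump.
#' @export
deserialize_forest <- function(path_or_json) {
  obj <- jsonlite::fromJSON(path_or_json, simplifyVector = TRUE)
  if (!identical(obj$format, "metayield_forest"))
    stop("not a metayield forest dump")
  structure(list(trees = obj$trees, feature_names = obj$feature_names,
                 feature_dim = length(obj$feature_names),
                 n_trees = obj$n_trees),
            class = "yield_forest_dump")
}

#' @export
tree_transform.yield_forest_dump <- function(forest, features) {
  features <- as.matrix(features)
  if (ncol(features) != forest$feature_dim)
    stop("feature dimension mismatch")
  out <- matrix(NA_real_, nrow(features), forest$n_trees)
  for (m in seq_len(forest$n_trees)) {
    tr <- if (is.data.frame(forest$trees)) {
      lapply(forest$trees, `[[`, m)            # jsonlite column-major form
    } else forest$trees[[m]]
    for (i in seq_len(nrow(features))) {
      node <- 1L
      while (!is.na(tr$splitvar[node])) {
        node <- if (features[i, tr$splitvar[node] + 1L] <= tr$splitval[node])
          tr$left[node] + 1L else tr$right[node] + 1L
      }
      out[i, m] <- tr$prediction[node]
    }
  }
  out
}
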