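# --- t-SNE -----------------------------------------------------------------
# Exact (non-Barnes-Hut) t-SNE, following the reference algorithm: Gaussian
# input similarities calibrated per point to a fixed perplexity by binary
# search, Student-t output similarities, gradient descent with momentum,
# adaptive per-parameter gains and early exaggeration. Group candidate sets
# here are a few hundred points, so the O(N^2) exact form is the right tool.

# conditional-probability row for one point given precision beta
.hbeta <- function(d2_row, beta) {
  p <- exp(-d2_row * beta)
  sump <- sum(p)
  if (sump < .Machine$double.xmin) {
    p <- rep(0, length(p)); sump <- 1
  }
  h <- log(sump) + beta * sum(d2_row * p) / sump
  list(H = h, P = p / sump)
}

.tsne_joint_p <- function(X, perplexity, tol = 1e-5, max_iter = 50L) {
  n <- nrow(X)
  sum_x <- rowSums(X^2)
  D2 <- pmax(outer(sum_x, sum_x, "+") - 2 * tcrossprod(X), 0)
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    di <- D2[i, -i]
    hb <- .hbeta(di, beta)
    diff <- hb$H - logU
    tries <- 0L
    while (abs(diff) > tol && tries < max_iter) {
      if (diff > 0) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
      hb <- .hbeta(di, beta)
      diff <- hb$H - logU
      tries <- tries + 1L
    }
    P[i, -i] <- hb$P
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Nonlinear dimension reduction (t-SNE)
#'
#' Maps high-dimensional reaction encodings to `out_dim` dimensions while
#' preserving local neighborhood structure, so that Euclidean distances in
#' the embedded space reflect the intrinsic geometry of the candidates before
#' Kennard-Stone selection. Deterministic for a fixed `config$seed`.
#'
#' @param X N x d numeric matrix (N >= 4).
#' @param config an [embed_config()].
#' @return N x `out_dim` coordinate matrix.
#' @export
tsne_reduce <- function(X, config = embed_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 points; skip the reduction below that")
  perplexity <- config$perplexity %||% min(50, floor((n - 1) / 3))
  if (perplexity >= n)
    stop("perplexity (", perplexity, ") must be smaller than N (", n, ")")
  set.seed(config$seed)
  P <- .tsne_joint_p(X, perplexity)
  Y <- matrix(rnorm(n * config$out_dim, sd = 1e-4), n)
  inc <- matrix(0, n, config$out_dim)
  gains <- matrix(1, n, config$out_dim)
  eta <- 500
  for (iter in seq_len(config$iterations)) {
    exag <- if (iter <= 100) 4 else 1
    momentum <- if (iter <= 20) 0.5 else 0.8
    sum_y <- rowSums(Y^2)
    num <- 1 / (1 + pmax(outer(sum_y, sum_y, "+") - 2 * tcrossprod(Y), 0))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (exag * P - Q) * num
    G <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- pmax(ifelse(sign(G) != sign(inc), gains + 0.2, gains * 0.8),
                  0.01)
    inc <- momentum * inc - eta * gains * G
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

# --- Kennard-Stone ----------------------------------------------------------

#' Kennard-Stone maximin selection
#'
#' Greedy design-of-experiment selection: the first two points are the pair
#' at maximal Euclidean distance; each subsequent point maximizes its minimum
#' distance to everything already selected, so the chosen subset covers the
#' space homogeneously. Ties are broken by lowest index (and the lower index
#' of the initial pair is emitted first), so the output is fully
#' deterministic.
#'
#' @param Z N x p numeric matrix of points (finite).
#' @param n number of points to select (2 <= n <= N).
#' @return integer vector of `n` distinct 1-based row indices, in selection
#'   order.
#' @export
kennard_stone <- function(Z, n) {
  Z <- as.matrix(Z)
  N <- nrow(Z)
  if (n < 2 || n > N) stop("n must satisfy 2 <= n <= N (N = ", N, ")")
  if (!all(is.finite(Z))) stop("points must be finite")
  D <- as.matrix(dist(Z))
  maxd <- max(D)
  hits <- which(D == maxd, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  sel <- c(hits[1, 1], hits[1, 2])
  remaining <- setdiff(seq_len(N), sel)
  while (length(sel) < n) {
    mind <- apply(D[remaining, sel, drop = FALSE], 1, min)
    pick <- remaining[which.max(mind)]   # which.max: first max = lowest index
    sel <- c(sel, pick)
    remaining <- setdiff(remaining, pick)
  }
  as.integer(sel)
}

# --- selection plans --------------------------------------------------------

#' Choose the few reactions of a group to measure
#'
#' For every candidate reaction of the group (all records with that group
#' value), embeds the feature vectors with [tsne_reduce()] and runs
#' [kennard_stone()] in the embedded space. The reduction is skipped — raw
#' features are used — when the feature dimension is already `<= out_dim` or
#' fewer than 4 candidates exist. Yields are never consulted: selection sees
#' features only.
#'
#' @param dataset a `reaction_dataset`.
#' @param group_value the group (additive) whose reactions are candidates.
#' @param n number of reactions to select.
#' @param config an [embed_config()].
#' @param use_tsne set `FALSE` to run Kennard-Stone on raw features.
#' @return an object of class `selection_plan`: `group_value`,
#'   `candidate_indices` (1-based dataset indices), `order` (the `n` selected
#'   indices in selection order) and `coords` (the coordinates used).
#' @export
select_fewshot <- function(dataset, group_value, n, config = embed_config(),
                           use_tsne = TRUE) {
  cand <- which(reaction_groups(dataset) == group_value)
  if (length(cand) < n)
    stop("group '", group_value, "' has only ", length(cand),
         " candidate reactions, need ", n)
  X <- reaction_features(dataset)[cand, , drop = FALSE]
  coords <- if (use_tsne && ncol(X) > config$out_dim && length(cand) >= 4)
    tsne_reduce(X, config) else X
  ord <- kennard_stone(coords, n)
  structure(list(group_value = group_value, candidate_indices = cand,
                 order = cand[ord], coords = coords),
            class = "selection_plan")
}

#' @export
print.selection_plan <- function(x, ...) {
  cat("selection_plan for group '", x$group_value, "': ",
      length(x$order), " of ", length(x$candidate_indices),
      " candidates\n  order: ", paste(x$order, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Write a selection plan as CSV
#'
#' One row per selected reaction: group, selection rank, 1-based dataset
#' index, and the embedded coordinates — the proposed experiment order in a
#' form chemists can read.
#'
#' @param plan a `selection_plan`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_selection_plan <- function(plan, path) {
  pos <- match(plan$order, plan$candidate_indices)
  co <- plan$coords[pos, , drop = FALSE]
  colnames(co) <- paste0("coord_", seq_len(ncol(co)))
  df <- data.frame(group = plan$group_value, rank = seq_along(plan$order),
                   dataset_index = plan$order, co, row.names = NULL)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
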