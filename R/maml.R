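#' Build the group-wise task pool consumed by the meta-learner
#'
#' Applies [tree_transform()] to the selected records (or uses raw features
#' when `forest` is `NULL`, the forest-free ablation) and splits the
#' (x', y) pairs by group value.
#'
#' @param dataset a `reaction_dataset`.
#' @param indices 1-based record indices forming the pool (training records).
#' @param forest a `yield_forest`, or `NULL` to use raw features.
#' @return named list: for each group value a list with `x` (matrix) and `y`.
#' @export
make_task_pool <- function(dataset, indices, forest = NULL) {
  g <- reaction_groups(dataset)[indices]
  x <- reaction_features(dataset)[indices, , drop = FALSE]
  if (!is.null(forest)) x <- tree_transform(forest, x)
  y <- reaction_yields(dataset)[indices]
  out <- lapply(split(seq_along(indices), g), function(i)
    list(x = x[i, , drop = FALSE], y = y[i]))
  out[unique(as.character(g))]
}

#' Sample a meta-learning task
#'
#' Draws one group uniformly among those with more than `K` pairs, then `K`
#' support pairs without replacement; the group's remaining pairs form the
#' query set.
#'
#' @param pool task pool from [make_task_pool()].
#' @param K support size.
#' @param seed optional seed; `NULL` draws from the current RNG state (used
#'   inside [meta_train()] so the whole trajectory depends on one seed).
#' @return list with `group_value`, `support` and `query` (each `x`, `y`).
#' @export
sample_task <- function(pool, K, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  sizes <- vapply(pool, function(p) length(p$y), integer(1))
  eligible <- names(pool)[sizes > K]
  if (length(eligible) == 0)
    stop("no group has more than K = ", K, " pairs")
  gv <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
  p <- pool[[gv]]
  idx <- sample(length(p$y), K)
  list(group_value = gv,
       support = list(x = p$x[idx, , drop = FALSE], y = p$y[idx]),
       query = list(x = p$x[-idx, , drop = FALSE], y = p$y[-idx]))
}

# Shared initial head: ensemble-mean bypass with the constant-unit scaling
# kappa calibrated on a probe task so one inner step transfers a unit
# support offset approximately one-to-one, or plain random initialization.
build_initial_head <- function(task_pool, input_dim, config, x_center,
                               x_scale, support_n = 5L) {
  if (!identical(config$init %||% "ensemble_mean", "ensemble_mean"))
    return(init_head(input_dim, config$hidden,
                     x_center = x_center, x_scale = x_scale))
  sizes <- vapply(task_pool, function(p) length(p$y), integer(1))
  probe <- task_pool[[which.max(sizes)]]
  k <- min(max(support_n, 2L), length(probe$y) - 1L)
  idx <- sample(length(probe$y), k)
  hseed <- sample.int(1e6, 1)   # same random capacity for every kappa
  best <- NULL
  for (kappa in c(0.1, 0.15, 0.2, 0.3, 0.5, 0.75, 1)) {
    h <- init_ensemble_head(input_dim, config$hidden, x_center, x_scale,
                            seed = hseed, kappa = kappa)
    g <- inner_step_gain(h, probe$x[idx, , drop = FALSE],
                         probe$x[-idx, , drop = FALSE], config$inner_lr)
    if (is.null(best) || abs(g - 1) < abs(best$g - 1))
      best <- list(head = h, g = g, kappa = kappa)
  }
  attr(best$head, "calibration") <- c(kappa = best$kappa, gain = best$g)
  best$head
}

# Adam step on a flat parameter vector; returns updated (theta, m, v)
adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  state
}

#' Meta-train the attention head (MAML)
#'
#' Each outer iteration samples `tasks_per_iteration` tasks; for each, one
#' inner gradient step on the support set yields adapted parameters, and the
#' outer objective is the sum over tasks of the query loss at those adapted
#' parameters. The outer objective is minimized with Adam. With
#' `second_order = TRUE` the outer gradient differentiates through the inner
#' step exactly.
#'
#' @param task_pool pool from [make_task_pool()], training groups only.
#' @param input_dim head input size (number of trees `M`, or the raw feature
#'   dimension in the forest-free ablation).
#' @param config a [meta_config()].
#' @param val_pool optional pool of validation group(s) — additives unseen
#'   by the forest. The mean post-adaptation query loss on them is logged
#'   every `config$val_every` iterations (including iteration 0), and with
#'   `config$select_best = TRUE` the checkpoint minimizing it is returned:
#'   the validation reagent decides how much meta-training helps one-step
#'   adaptation, exactly what a held-out reagent is reserved for.
#' @param val_support support-set size used when scoring validation
#'   adaptation (the deployment few-shot size).
#' @return an `attention_head` carrying attributes `objective_log` (outer
#'   objective per iteration), `val_log` (iteration, post-adaptation loss)
#'   and `selected_iteration`.
#' @export
meta_train <- function(task_pool, input_dim, config = meta_config(),
                       val_pool = NULL, val_support = 5L) {
  if (length(task_pool) == 0) stop("empty task pool")
  set.seed(config$seed)
  x_center <- x_scale <- NULL
  if (isTRUE(config$standardize)) {
    x_all <- do.call(rbind, lapply(task_pool, `[[`, "x"))
    x_center <- colMeans(x_all)
    s <- apply(x_all, 2, sd)
    x_scale <- ifelse(s > 0, s, 1)
  }
  head <- build_initial_head(task_pool, input_dim, config, x_center, x_scale,
                             val_support)
  template <- head$layers
  theta <- flatten_params(template)
  state <- list(theta = theta, m = numeric(length(theta)),
                v = numeric(length(theta)), t = 0L)
  # cap the support size so tasks exist in scarce-data regimes (a training
  # group must retain at least one query pair)
  sizes <- vapply(task_pool, function(p) length(p$y), integer(1))
  K <- min(config$support_size, max(sizes) - 1L)
  if (K < 1) stop("every training group has fewer than 2 pairs")
  obj_log <- numeric(config$meta_iterations)
  val_log <- list()
  # fixed support/query partition of each validation group, so checkpoint
  # scores are comparable across iterations
  val_splits <- NULL
  if (!is.null(val_pool)) {
    val_splits <- lapply(val_pool, function(p) {
      k <- min(val_support, length(p$y) - 1L)
      idx <- sample(length(p$y), k)
      list(sx = p$x[idx, , drop = FALSE], sy = p$y[idx],
           qx = p$x[-idx, , drop = FALSE], qy = p$y[-idx])
    })
  }
  score_val <- function(h) mean(vapply(val_splits, function(v) {
    a <- inner_update(h, v$sx, v$sy, config$inner_lr)
    task_loss(a, v$qx, v$qy)
  }, numeric(1)))
  best <- list(layers = head$layers, loss = Inf, iteration = 0L)
  if (!is.null(val_splits)) {
    vl <- score_val(head)
    val_log[[1L]] <- c(iteration = 0, loss = vl)
    best <- list(layers = head$layers, loss = vl, iteration = 0L)
  }
  for (it in seq_len(config$meta_iterations)) {
    total <- numeric(length(theta))
    obj <- 0
    for (j in seq_len(config$tasks_per_iteration)) {
      task <- sample_task(task_pool, K)
      g <- outer_gradient(head, task$support$x, task$support$y,
                          task$query$x, task$query$y,
                          config$inner_lr, config$second_order)
      total <- total + flatten_params(g)
      adapted <- inner_update(head, task$support$x, task$support$y,
                              config$inner_lr)
      obj <- obj + task_loss(adapted, task$query$x, task$query$y)
    }
    state <- adam_step(state$theta, total, state, config$outer_lr)
    head$layers <- unflatten_params(state$theta, template)
    obj_log[it] <- obj
    if (!is.null(val_splits) &&
        (it %% config$val_every == 0 || it == config$meta_iterations)) {
      vl <- score_val(head)
      val_log[[length(val_log) + 1L]] <- c(iteration = it, loss = vl)
      if (vl < best$loss)
        best <- list(layers = head$layers, loss = vl, iteration = it)
    }
  }
  selected <- config$meta_iterations
  if (!is.null(val_splits) && isTRUE(config$select_best %||% TRUE)) {
    head$layers <- best$layers
    selected <- best$iteration
  }
  attr(head, "objective_log") <- obj_log
  attr(head, "val_log") <- if (length(val_log)) do.call(rbind, val_log)
  attr(head, "selected_iteration") <- selected
  head
}

#' Predict yields with forest + attention head
#'
#' Composes the per-tree transform and the head: predictions are
#' `f_theta(tree_transform(forest, features))` row-wise. With `forest = NULL`
#' the head is applied to the raw features (forest-free ablation).
#'
#' @param forest a `yield_forest` or `NULL`.
#' @param head an `attention_head`.
#' @param features N x d feature matrix.
#' @param clip clip predictions to the physical yield range \[0, 100\].
#' @return numeric prediction vector (percent scale).
#' @export
predict_yield <- function(forest, head, features, clip = FALSE) {
  x <- if (is.null(forest)) as.matrix(features)
       else tree_transform(forest, features)
  p <- head_predict(head, x)
  if (clip) p <- pmin(pmax(p, 0), 100)
  p
}
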