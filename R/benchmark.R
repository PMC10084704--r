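# Internal engine for one seed of the few-shot protocol. All methods share
# it: the attention-head route (MAML or transfer pretraining, forest or raw
# features) and the enlarged-training-set forest baseline. Support reactions
# are never part of query metrics, for every method.

derive_seed <- function(seed, offset) as.integer((seed * 1009L + offset) %% .Machine$integer.max)

pooled_metrics <- function(y_true, y_pred)
  c(r2 = r2(y_true, y_pred), rmse = rmse(y_true, y_pred),
    mae = mae(y_true, y_pred))

# pretraining-and-fine-tuning head: ordinary pooled minibatch regression on
# the training groups (no inner loop), the transfer-learning ablation
pretrain_head <- function(task_pool, input_dim, config) {
  set.seed(config$seed)
  x_all <- do.call(rbind, lapply(task_pool, `[[`, "x"))
  y_all <- unlist(lapply(task_pool, `[[`, "y"), use.names = FALSE)
  x_center <- x_scale <- NULL
  if (isTRUE(config$standardize)) {
    x_center <- colMeans(x_all)
    s <- apply(x_all, 2, sd)
    x_scale <- ifelse(s > 0, s, 1)
  }
  head <- build_initial_head(task_pool, input_dim, config, x_center, x_scale)
  template <- head$layers
  theta <- flatten_params(template)
  state <- list(theta = theta, m = numeric(length(theta)),
                v = numeric(length(theta)), t = 0L)
  for (it in seq_len(config$meta_iterations)) {
    idx <- sample(length(y_all), min(config$support_size, length(y_all)))
    g <- head_gradient(head$layers, x_all[idx, , drop = FALSE], y_all[idx])
    state <- adam_step(state$theta, flatten_params(g), state, config$outer_lr)
    head$layers <- unflatten_params(state$theta, template)
  }
  head
}

select_supports <- function(dataset, group_value, n_finetune, sampling,
                            ec, rep_seed) {
  cand <- which(reaction_groups(dataset) == group_value)
  if (n_finetune == 0) return(integer(0))
  if (sampling == "ks") {
    select_fewshot(dataset, group_value, n_finetune, ec)$order
  } else {
    set.seed(rep_seed)
    sample(cand, n_finetune)
  }
}

eval_fewshot_seed <- function(dataset, split, seed, n_finetune,
                              fc, mc, ec,
                              method = c("metarf", "rf_baseline"),
                              head_training = c("maml", "transfer"),
                              use_forest = TRUE,
                              sampling = c("ks", "random"),
                              sampling_reps = 1L, clip = FALSE,
                              k_top = 10L) {
  method <- match.arg(method)
  head_training <- match.arg(head_training)
  sampling <- match.arg(sampling)
  fc$seed <- derive_seed(seed, 1L)
  mc$seed <- derive_seed(seed, 2L)
  idx <- split_indices(dataset, split)
  x_all <- reaction_features(dataset)
  y_all <- reaction_yields(dataset)

  forest <- head <- NULL
  if (use_forest)
    forest <- fit_forest(x_all[idx$train, , drop = FALSE], y_all[idx$train],
                         fc)
  if (method == "metarf") {
    pool <- make_task_pool(dataset, idx$train, forest)
    input_dim <- ncol(pool[[1]]$x)
    val_pool <- if (length(idx$val) > 0)
      make_task_pool(dataset, idx$val, forest)
    head <- if (head_training == "maml")
      meta_train(pool, input_dim, mc, val_pool = val_pool,
                 val_support = max(n_finetune, 1L))
      else pretrain_head(pool, input_dim, mc)
  }

  test_groups <- split$test_groups
  sizes <- table(reaction_groups(dataset))[as.character(test_groups)]
  keep <- sizes >= n_finetune + 1
  if (any(!keep))
    warning("skipping test group(s) smaller than n_finetune + 1: ",
            paste(test_groups[!keep], collapse = ", "))
  test_groups <- test_groups[keep]
  if (length(test_groups) == 0) stop("no evaluable test group")

  reps <- vector("list", sampling_reps)
  for (rep in seq_len(sampling_reps)) {
    supports <- lapply(seq_along(test_groups), function(gi) {
      ec_g <- ec
      ec_g$seed <- derive_seed(seed, 10L + gi)
      select_supports(dataset, test_groups[gi], n_finetune, sampling, ec_g,
                      rep_seed = derive_seed(seed, 1000L * rep + gi))
    })
    names(supports) <- as.character(test_groups)

    if (method == "rf_baseline") {
      enlarged <- c(idx$train, unlist(supports, use.names = FALSE))
      fc_b <- fc
      fc_b$seed <- derive_seed(seed, 5L)
      forest_b <- fit_forest(x_all[enlarged, , drop = FALSE], y_all[enlarged],
                             fc_b)
    }

    per_group <- vector("list", length(test_groups))
    pooled_true <- pooled_pred <- pooled_pre <- numeric(0)
    for (gi in seq_along(test_groups)) {
      gv <- test_groups[gi]
      cand <- which(reaction_groups(dataset) == gv)
      sup <- supports[[gi]]
      query <- setdiff(cand, sup)
      yq <- y_all[query]
      if (method == "rf_baseline") {
        pred <- forest_predict(forest_b, x_all[query, , drop = FALSE])
        pre <- pred
      } else {
        xq <- if (use_forest)
          tree_transform(forest, x_all[query, , drop = FALSE])
          else x_all[query, , drop = FALSE]
        pre <- head_predict(head, xq)
        if (n_finetune > 0) {
          xs <- if (use_forest)
            tree_transform(forest, x_all[sup, , drop = FALSE])
            else x_all[sup, , drop = FALSE]
          head_g <- fine_tune(head, xs, y_all[sup], mc$inner_lr)
          pred <- head_predict(head_g, xq)
        } else pred <- pre
      }
      if (clip) {
        pred <- pmin(pmax(pred, 0), 100)
        pre <- pmin(pmax(pre, 0), 100)
      }
      per_group[[gi]] <- data.frame(
        group = as.character(gv), n_query = length(query),
        r2 = tryCatch(r2(yq, pred), error = function(e) NA_real_),
        rmse = rmse(yq, pred), mae = mae(yq, pred),
        rmse_pre = rmse(yq, pre), stringsAsFactors = FALSE)
      pooled_true <- c(pooled_true, yq)
      pooled_pred <- c(pooled_pred, pred)
      pooled_pre <- c(pooled_pre, pre)
    }
    groups_df <- do.call(rbind, per_group)
    reps[[rep]] <- list(
      groups = groups_df,
      pooled = pooled_metrics(pooled_true, pooled_pred),
      pooled_pre = pooled_metrics(pooled_true, pooled_pre),
      topk = list(
        predicted = topk_selection(pooled_true, pooled_pred,
                                   min(k_top, length(pooled_true))),
        ideal = topk_selection(pooled_true, pooled_pred,
                               min(k_top, length(pooled_true)),
                               mode = "ideal"),
        random = topk_selection(pooled_true, pooled_pred,
                                min(k_top, length(pooled_true)),
                                mode = "random",
                                seed = derive_seed(seed, 7L))),
      supports = supports)
  }
  pooled_mat <- do.call(rbind, lapply(reps, `[[`, "pooled"))
  pre_mat <- do.call(rbind, lapply(reps, `[[`, "pooled_pre"))
  list(seed = seed,
       pooled = colMeans(pooled_mat),
       pooled_pre = colMeans(pre_mat),
       groups = reps[[1]]$groups,
       topk = reps[[1]]$topk,
       reps = reps)
}

#' Run the leave-reagent-out few-shot benchmark
#'
#' The full protocol, repeated per seed. For `method = "metarf"`: fit the
#' forest on the training groups, meta-train the attention head over
#' training-group tasks, then per test group select `n_finetune` support
#' reactions (t-SNE + Kennard-Stone by default), fine-tune with one gradient
#' step and predict the group's remaining reactions. For
#' `method = "rf_baseline"`: add the same support reactions to the training
#' set, refit the forest and predict with the ensemble mean — the fairness
#' rule giving both methods identical training information. Metrics are
#' pooled over the union of all test-group query reactions; support
#' reactions never enter metrics.
#'
#' @param dataset a `reaction_dataset`.
#' @param split a `split_spec` with at least one test group.
#' @param method `"metarf"` or `"rf_baseline"`.
#' @param n_finetune support reactions per test group (0 = zero-shot).
#' @param seeds integer vector; the protocol is repeated per seed and every
#'   source of randomness derives from it.
#' @param forest_config,meta_config,embed_config component configurations
#'   (their `seed` fields are overridden by values derived from each
#'   benchmark seed).
#' @param sampling `"ks"` (t-SNE + Kennard-Stone) or `"random"`. `NULL`
#'   resolves to `"ks"` for `metarf` and `"random"` for `rf_baseline`: the
#'   representative-sampling procedure is part of the proposed method, and
#'   the published baseline receives randomly selected fine-tune samples.
#' @param sampling_reps repetitions of the support draw (averaged; used with
#'   random sampling).
#' @param clip clip predictions to \[0, 100\].
#' @param k_top k of the top-k high-yield selection summary.
#' @return an object of class `benchmark_result`: per-seed results, a
#'   `summary` data frame (one row per seed) and `aggregate` mean metrics.
#' @export
run_fewshot_benchmark <- function(dataset, split,
                                  method = c("metarf", "rf_baseline"),
                                  n_finetune = 5L, seeds = 1:5,
                                  forest_config = metayield::forest_config(),
                                  meta_config = metayield::meta_config(),
                                  embed_config = metayield::embed_config(),
                                  sampling = NULL,
                                  sampling_reps = 1L, clip = FALSE,
                                  k_top = 10L) {
  method <- match.arg(method)
  sampling <- if (is.null(sampling)) {
    if (method == "rf_baseline") "random" else "ks"
  } else match.arg(sampling, c("ks", "random"))
  if (length(split$test_groups) == 0) stop("split has no test groups")
  per_seed <- lapply(seeds, function(s)
    eval_fewshot_seed(dataset, split, s, n_finetune, forest_config,
                      meta_config, embed_config, method = method,
                      sampling = sampling, sampling_reps = sampling_reps,
                      clip = clip, k_top = k_top))
  finalize_benchmark(per_seed, method, n_finetune, seeds)
}

finalize_benchmark <- function(per_seed, label, n_finetune, seeds) {
  summary <- do.call(rbind, lapply(per_seed, function(r)
    data.frame(seed = r$seed, r2 = r$pooled[["r2"]],
               rmse = r$pooled[["rmse"]], mae = r$pooled[["mae"]],
               r2_pre = r$pooled_pre[["r2"]],
               rmse_pre = r$pooled_pre[["rmse"]],
               topk_mean = r$topk$predicted$mean,
               topk_sd = r$topk$predicted$sd,
               topk_ideal_mean = r$topk$ideal$mean,
               topk_random_mean = r$topk$random$mean)))
  structure(list(method = label, n_finetune = n_finetune, seeds = seeds,
                 per_seed = per_seed, summary = summary,
                 aggregate = colMeans(summary[, -1, drop = FALSE])),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    "benchmark_result: %s (n_finetune = %d, %d seed%s)\n  R2 = %.4f  RMSE = %.4f  MAE = %.4f\n  top-k true-yield mean = %.1f (ideal %.1f, random %.1f)\n",
    x$method, x$n_finetune, length(x$seeds),
    if (length(x$seeds) > 1) "s" else "", a[["r2"]], a[["rmse"]], a[["mae"]],
    a[["topk_mean"]], a[["topk_ideal_mean"]], a[["topk_random_mean"]]))
  invisible(x)
}

#' Run an ablation variant of the model
#'
#' Variants of the full model isolating each component:
#' `metarf_random_sampling` replaces the t-SNE + Kennard-Stone support
#' selection with seeded uniform draws, averaged over `sampling_reps`
#' repetitions (10 by default); `maml_on_raw_features` removes the random
#' forest and feeds raw reaction encodings to the meta-learned head;
#' `transfer_head` trains the head by ordinary pooled regression on the
#' training groups (standard pretraining) and applies the same one-step
#' fine-tune; `transfer_head_random_sampling` combines the last two changes.
#'
#' @inheritParams run_fewshot_benchmark
#' @param variant one of `"metarf_random_sampling"`, `"maml_on_raw_features"`,
#'   `"transfer_head"`, `"transfer_head_random_sampling"`.
#' @param sampling_reps repetitions of the random support draw.
#' @return a `benchmark_result`.
#' @export
run_ablation <- function(dataset, split, variant, n_finetune = 5L,
                         seeds = 1:5,
                         forest_config = metayield::forest_config(),
                         meta_config = metayield::meta_config(),
                         embed_config = metayield::embed_config(),
                         sampling_reps = 10L, clip = FALSE, k_top = 10L) {
  spec <- switch(variant,
    metarf_random_sampling =
      list(head_training = "maml", use_forest = TRUE, sampling = "random",
           reps = sampling_reps),
    maml_on_raw_features =
      list(head_training = "maml", use_forest = FALSE, sampling = "ks",
           reps = 1L),
    transfer_head =
      list(head_training = "transfer", use_forest = TRUE, sampling = "ks",
           reps = 1L),
    transfer_head_random_sampling =
      list(head_training = "transfer", use_forest = TRUE, sampling = "random",
           reps = sampling_reps),
    stop("unknown ablation variant '", variant, "'"))
  per_seed <- lapply(seeds, function(s)
    eval_fewshot_seed(dataset, split, s, n_finetune, forest_config,
                      meta_config, embed_config, method = "metarf",
                      head_training = spec$head_training,
                      use_forest = spec$use_forest, sampling = spec$sampling,
                      sampling_reps = spec$reps, clip = clip, k_top = k_top))
  finalize_benchmark(per_seed, variant, n_finetune, seeds)
}
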