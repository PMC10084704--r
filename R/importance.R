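#' Permutation-and-retrain feature importance
#'
#' Importance of a feature block is the decrease in pooled test R-squared
#' when the block's values are randomly shuffled across reactions and the
#' *entire* model — forest, meta-trained head, per-group fine-tune — is
#' retrained on the shuffled data. Shuffling is joint across the block's
#' columns (one row permutation per repeat), destroying the block's
#' association with yield while preserving its marginal distribution.
#'
#' @param dataset a `reaction_dataset`.
#' @param split a `split_spec`.
#' @param feature_blocks named list of integer column-index vectors that
#'   partition `1:ncol(reaction_features(dataset))`; single columns or
#'   semantic groups (e.g. one role's informative descriptors) both work —
#'   see [role_feature_blocks()].
#' @param n_finetune support reactions per test group.
#' @param seeds integer vector; the whole procedure repeats per seed.
#' @param repeats shuffles per block and seed (importance averages over
#'   them).
#' @param forest_config,meta_config,embed_config model configurations.
#' @param sampling support-selection mode passed to the evaluation engine.
#' @return data frame with one row per block: `block`, `importance`
#'   (`r2_intact - mean r2_shuffled`), `r2_intact`, `r2_shuffled`, `sd`, and
#'   `rank`; rows ordered by decreasing importance.
#' @export
permutation_importance <- function(dataset, split, feature_blocks,
                                   n_finetune = 5L, seeds = 1L,
                                   repeats = 3L,
                                   forest_config = metayield::forest_config(),
                                   meta_config = metayield::meta_config(),
                                   embed_config = metayield::embed_config(),
                                   sampling = "random") {
  cols <- sort(unlist(feature_blocks, use.names = FALSE))
  if (!identical(cols, seq_len(ncol(reaction_features(dataset)))))
    stop("feature_blocks must partition the feature columns")
  if (is.null(names(feature_blocks)))
    stop("feature_blocks must be named")

  run_r2 <- function(ds, s)
    eval_fewshot_seed(ds, split, s, n_finetune, forest_config, meta_config,
                      embed_config, method = "metarf",
                      sampling = sampling)$pooled[["r2"]]

  r2_intact <- mean(vapply(seeds, function(s) run_r2(dataset, s), numeric(1)))

  rows <- lapply(names(feature_blocks), function(bn) {
    block <- feature_blocks[[bn]]
    vals <- unlist(lapply(seeds, function(s) {
      vapply(seq_len(repeats), function(rep) {
        # seed from the block *name* so results don't depend on block order
        set.seed(derive_seed(s, 50000L + rep * 101L + sum(utf8ToInt(bn))))
        ds <- dataset
        perm <- sample(nrow(ds$features))
        ds$features[, block] <- ds$features[perm, block, drop = FALSE]
        run_r2(ds, s)
      }, numeric(1))
    }))
    data.frame(block = bn, importance = r2_intact - mean(vals),
               r2_intact = r2_intact, r2_shuffled = mean(vals),
               sd = sd(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$importance), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
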