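#' Random-forest configuration
#'
#' Hyperparameters of the regression forest whose per-tree outputs feed the
#' attention head. Defaults follow standard random-forest regression practice:
#' 100 trees, `max_features = floor(d/3)` candidate features per node,
#' leaves down to a single sample, bootstrap resampling.
#'
#' @param n_trees number of trees `M` (>= 1).
#' @param max_features number of features tried at each split; `NULL` means
#'   `max(1, floor(d/3))` where `d` is the feature dimension at fit time.
#' @param min_leaf minimum number of samples per leaf (>= 1). Setting it to
#'   the training-set size forces single-leaf trees that predict the mean.
#' @param bootstrap fit each tree on a bootstrap resample (`TRUE`) or on the
#'   full training set (`FALSE`).
#' @param max_depth maximum tree depth; `NULL` for unlimited.
#' @param seed integer seed controlling all randomness in the fit.
#' @return an object of class `forest_config`.
#' @seealso [fit_forest()]
#' @export
forest_config <- function(n_trees = 100L, max_features = NULL, min_leaf = 1L,
                          bootstrap = TRUE, max_depth = NULL, seed = 1L) {
  stopifnot(n_trees >= 1, min_leaf >= 1, is.logical(bootstrap))
  if (!is.null(max_features)) stopifnot(max_features >= 1)
  if (!is.null(max_depth)) stopifnot(max_depth >= 1)
  structure(list(n_trees = as.integer(n_trees), max_features = max_features,
                 min_leaf = as.integer(min_leaf), bootstrap = bootstrap,
                 max_depth = max_depth, seed = as.integer(seed)),
            class = "forest_config")
}

#' Meta-learning configuration
#'
#' Settings of the MAML loop that trains the attention head: one inner
#' gradient step of size `inner_lr` per task, an Adam outer optimizer, and
#' `meta_iterations` outer iterations. Defaults are the published training
#' recipe for this model: 80 iterations, support size `K = 40`, inner
#' learning rate `1e-4`; outer step size 0.001 is Adam's common default.
#'
#' @param inner_lr step size `alpha` of the inner/fine-tune gradient step
#'   (>= 0). The same value is used during meta-training and few-shot
#'   fine-tuning.
#' @param outer_lr Adam step size of the outer loop.
#' @param meta_iterations number of outer iterations (>= 0).
#' @param support_size support-set size `K` per sampled task.
#' @param tasks_per_iteration meta-batch size (tasks summed per outer step).
#' @param second_order differentiate through the inner step (exact MAML)
#'   rather than the first-order approximation.
#' @param hidden integer vector of hidden-layer widths of the head;
#'   `integer(0)` gives a linear head.
#' @param seed integer seed for initialization and task sampling.
#' @param val_every log validation loss every this many iterations when a
#'   validation pool is supplied to [meta_train()].
#' @param select_best when a validation pool is supplied to [meta_train()],
#'   return the checkpoint with the lowest post-adaptation validation loss
#'   instead of the final iterate.
#' @param standardize standardize head inputs per column (statistics from the
#'   meta-training pool) before the first layer. On by default; the bypass
#'   initialization below re-expresses the ensemble-mean prediction in the
#'   standardized coordinates, so targets and predictions stay on the
#'   percent scale throughout.
#' @param init `"ensemble_mean"` (default) starts the head as an exact
#'   bypass of the uniform tree average — the plain random-forest
#'   predictor — plus small random capacity, so meta-learning refines the
#'   attention weights from the baseline model and the inner-step gain
#'   through the bypass unit (`2 * inner_lr * mean_yield^2`, about 1 on the
#'   percent scale) is calibrated for one-step offset adaptation;
#'   `"random"` uses plain seeded random initialization.
#' @return an object of class `meta_config`.
#' @export
meta_config <- function(inner_lr = 1e-4, outer_lr = 1e-3,
                        meta_iterations = 80L, support_size = 40L,
                        tasks_per_iteration = 1L, second_order = TRUE,
                        hidden = c(40L, 40L), seed = 1L, val_every = 10L,
                        select_best = TRUE, standardize = TRUE,
                        init = c("ensemble_mean", "random")) {
  stopifnot(inner_lr >= 0, outer_lr > 0, meta_iterations >= 0,
            support_size >= 1, tasks_per_iteration >= 1,
            is.logical(second_order), all(hidden >= 1) || length(hidden) == 0)
  structure(list(inner_lr = inner_lr, outer_lr = outer_lr,
                 meta_iterations = as.integer(meta_iterations),
                 support_size = as.integer(support_size),
                 tasks_per_iteration = as.integer(tasks_per_iteration),
                 second_order = second_order, hidden = as.integer(hidden),
                 seed = as.integer(seed), val_every = as.integer(val_every),
                 select_best = select_best, standardize = standardize,
                 init = match.arg(init)),
            class = "meta_config")
}

#' Embedding configuration for sample selection
#'
#' Settings of the t-SNE reduction run before Kennard-Stone selection.
#' `perplexity = NULL` resolves to `min(50, floor((N - 1) / 3))` at fit
#' time: as large as the standard perplexity range allows, so that
#' neighborhoods span whole structural families and the map preserves
#' between-family geometry (what Kennard-Stone needs), while staying well
#' below the candidate count.
#'
#' @param out_dim target dimension (default 2).
#' @param perplexity neighborhood scale; must be `< N`.
#' @param iterations gradient-descent iterations of the embedding optimizer.
#' @param seed integer seed for the random initialization.
#' @return an object of class `embed_config`.
#' @seealso [tsne_reduce()], [select_fewshot()]
#' @export
embed_config <- function(out_dim = 2L, perplexity = NULL, iterations = 300L,
                         seed = 1L) {
  stopifnot(out_dim >= 1, iterations >= 1)
  if (!is.null(perplexity)) stopifnot(perplexity > 0)
  structure(list(out_dim = as.integer(out_dim), perplexity = perplexity,
                 iterations = as.integer(iterations), seed = as.integer(seed)),
            class = "embed_config")
}

#' Synthetic reaction-space configuration
#'
#' Defines a combinatorial high-throughput-experimentation style reaction
#' space with known ground truth. The default shape mirrors a Pd-catalysed
#' coupling screen: 15 aryl halides x 4 ligands x 3 bases x 22 additives
#' (3960 reactions in the full cross), 20 descriptor dimensions per role of
#' which the first `n_informative` carry signal. Yields are
#' `base_yield + role main effects + pairwise interactions + additive-specific
#' shift + Gaussian noise`, clipped to \[0, 100\].
#'
#' The additive-specific shift is a fixed linear map of the additive's
#' informative descriptor dimensions, so few-shot adaptation to a new additive
#' is learnable from descriptors plus support yields. Components of the first
#' non-group role carry `cluster_k` planted descriptor clusters (offset scale
#' `cluster_sep`), giving each additive's candidate reactions a known cluster
#' structure for sampling experiments.
#'
#' @param roles named integer vector: components per role, in concatenation
#'   order. The default is `c(aryl_halide = 15, ligand = 4, base = 3,
#'   additive = 22)`.
#' @param descriptor_dim descriptor length per role (scalar, recycled).
#' @param group_role role whose values define tasks/groups.
#' @param n_informative number of leading descriptor dimensions per role that
#'   carry the component's latent effect.
#' @param signal_loading loading of the latent component effect on each
#'   informative dimension; informative dimensions have variance
#'   `1 + signal_loading^2` versus 1 for noise dimensions.
#' @param effect_scale standard deviation (percent yield) of the
#'   group-specific shift across components of `group_role`.
#' @param main_effect_scale standard deviation (percent) of each non-group
#'   role's main effect; `NULL` means `effect_scale / 2`, so zeroing
#'   `effect_scale` removes all component effects.
#' @param interaction_scale standard deviation (percent) of the summed
#'   cross-role interaction term.
#' @param noise_sd standard deviation (percent) of the measurement noise.
#' @param base_yield grand-mean yield (percent).
#' @param cluster_k planted descriptor clusters in the first non-group role
#'   (0 disables).
#' @param cluster_sep per-dimension standard deviation of the cluster mean
#'   offsets on informative dimensions.
#' @param shift_dims descriptor dimensions of `group_role` that carry the
#'   group shift. `NULL` (default) spreads the shift as a dense linear map
#'   over the whole descriptor, so no single dimension identifies an
#'   additive's effect; an integer vector plants it sparsely (used e.g. for
#'   importance-recovery experiments).
#' @param seed integer seed; fixing it makes the generated dataset
#'   bit-reproducible.
#' @return an object of class `synth_config`.
#' @seealso [gen_components()], [gen_dataset()]
#' @export
synth_config <- function(roles = c(aryl_halide = 15L, ligand = 4L,
                                   base = 3L, additive = 22L),
                         descriptor_dim = 20L, group_role = "additive",
                         n_informative = 3L, signal_loading = 1,
                         effect_scale = 15, main_effect_scale = NULL,
                         interaction_scale = 10, noise_sd = 5,
                         base_yield = 50, cluster_k = 4L, cluster_sep = 12,
                         shift_dims = NULL, seed = 1L) {
  stopifnot(length(roles) >= 2, all(roles >= 1), !is.null(names(roles)),
            group_role %in% names(roles), noise_sd >= 0, effect_scale >= 0,
            interaction_scale >= 0, cluster_k >= 0, n_informative >= 1)
  descriptor_dim <- rep_len(as.integer(descriptor_dim), length(roles))
  names(descriptor_dim) <- names(roles)
  stopifnot(all(n_informative <= descriptor_dim))
  if (!is.null(shift_dims))
    stopifnot(all(shift_dims >= 1),
              all(shift_dims <= descriptor_dim[[group_role]]))
  structure(list(roles = vapply(roles, as.integer, integer(1)),
                 descriptor_dim = descriptor_dim, group_role = group_role,
                 n_informative = as.integer(n_informative),
                 signal_loading = signal_loading, effect_scale = effect_scale,
                 main_effect_scale = main_effect_scale,
                 interaction_scale = interaction_scale, noise_sd = noise_sd,
                 base_yield = base_yield, cluster_k = as.integer(cluster_k),
                 cluster_sep = cluster_sep,
                 shift_dims = if (!is.null(shift_dims)) as.integer(shift_dims),
                 seed = as.integer(seed)),
            class = "synth_config")
}
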