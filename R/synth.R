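#' Generate component descriptor tables
#'
#' Each component receives a latent effect `u ~ N(0, 1)` and a descriptor
#' vector of standard-normal entries; the informative dimensions additionally
#' carry `signal_loading * u`, so informative dimensions have variance
#' `1 + signal_loading^2` versus 1. Components of the first non-group role
#' get planted cluster offsets on their informative dimensions when
#' `cluster_k > 0`. Deterministic for a fixed `config$seed`.
#'
#' @param config a [synth_config()].
#' @return named list (one element per role) with `values` (n x dim matrix,
#'   component ids as row names), `u` (latent effects), `cluster` (labels, or
#'   `NULL`) and `value_names`.
#' @export
gen_components <- function(config) {
  set.seed(config$seed)
  cluster_role <- if (config$cluster_k > 0)
    setdiff(names(config$roles), config$group_role)[1] else NA_character_
  out <- lapply(names(config$roles), function(r) {
    n <- config$roles[[r]]
    d <- config$descriptor_dim[[r]]
    inf <- seq_len(config$n_informative)
    u <- rnorm(n)
    values <- matrix(rnorm(n * d), n, d)
    cluster <- NULL
    if (identical(r, cluster_role)) {
      # descriptor clusters are reactivity clusters: components of a cluster
      # share half of their latent-effect variance (structurally similar
      # reagents behave similarly), so covering clusters is informative
      cluster <- rep_len(seq_len(config$cluster_k), n)
      u_mu <- rnorm(config$cluster_k)
      u <- sqrt(0.5) * u_mu[cluster] + sqrt(0.5) * u
      mu <- matrix(rnorm(config$cluster_k * length(inf), sd = config$cluster_sep),
                   config$cluster_k)
      values[, inf] <- values[, inf] + mu[cluster, , drop = FALSE]
    }
    values[, inf] <- values[, inf] + config$signal_loading * u
    rownames(values) <- sprintf("%s_%02d", r, seq_len(n))
    colnames(values) <- sprintf("d%02d", seq_len(d))
    list(values = values, u = u, cluster = cluster,
         value_names = colnames(values))
  })
  names(out) <- names(config$roles)
  out
}

#' Size of the combinatorial reaction space
#'
#' @param config a [synth_config()].
#' @return the product of the per-role component counts, as a double (sparse
#'   real-world spaces can exceed integer range).
#' @export
space_size <- function(config) prod(as.double(config$roles))

#' Generate a synthetic combinatorial reaction dataset with ground truth
#'
#' Emulates a high-throughput experimentation screen: the reaction space is
#' the full cross of the configured components (`coverage = "full"`), or a
#' uniform without-replacement sample of it (`coverage` a fraction, the
#' sparse electronic-lab-notebook regime). Yields are
#' `base + sum of role main effects + interactions + group shift + noise`,
#' clipped to \[0, 100\]. The group shift is a fixed linear map of the group
#' component's informative descriptor dimensions; non-group main effects are
#' proportional to the component latent `u`; interactions are pairwise
#' products of latents.
#'
#' @param config a [synth_config()].
#' @param coverage `"full"` or a fraction in (0, 1].
#' @return list with `dataset` (a `reaction_dataset`) and `truth`, which
#'   records every latent quantity: per-group shifts, per-component main
#'   effects, interaction coefficients, the per-record deterministic yield
#'   `effect_sum` (before noise and clipping), per-record cluster labels and
#'   the clipped fraction.
#' @export
gen_dataset <- function(config, coverage = "full") {
  comps <- gen_components(config)
  set.seed(config$seed + 1L)
  roles <- names(config$roles)
  sizes <- config$roles
  total <- space_size(config)

  # group shift: unit-norm linear map of the group component's descriptor.
  # By default the map is dense over the whole descriptor (no single
  # dimension identifies the additive's effect, as with real quantum
  # descriptors); shift_dims restricts it to a sparse planted subset.
  sdims <- config$shift_dims %||%
    seq_len(config$descriptor_dim[[config$group_role]])
  w <- rnorm(length(sdims))
  w <- w / sqrt(sum(w^2))
  dim_var <- ifelse(sdims <= config$n_informative,
                    1 + config$signal_loading^2, 1)
  zg <- comps[[config$group_role]]$values[, sdims, drop = FALSE]
  shift <- config$effect_scale * as.vector(zg %*% w) /
    sqrt(sum(w^2 * dim_var))
  names(shift) <- rownames(comps[[config$group_role]]$values)

  main_scale <- config$main_effect_scale %||% (config$effect_scale / 2)
  mains <- lapply(roles, function(r) {
    if (r == config$group_role) return(NULL)
    e <- main_scale * comps[[r]]$u
    names(e) <- rownames(comps[[r]]$values)
    e
  })
  names(mains) <- roles

  pairs <- utils::combn(roles, 2)
  icoef <- rnorm(ncol(pairs))

  # enumerate or sample combination indices (first role varies fastest)
  if (identical(coverage, "full")) {
    if (total > 1e7) stop("full cross too large to enumerate (", total, ")")
    lin <- seq_len(total) - 1
  } else {
    stopifnot(is.numeric(coverage), coverage > 0, coverage <= 1)
    m <- max(1L, round(coverage * total))
    if (total > .Machine$integer.max)
      stop("space too large to sample by index")
    lin <- sort(sample.int(total, m)) - 1
  }
  radix <- cumprod(c(1, sizes[-length(sizes)]))
  combo <- sapply(seq_along(roles), function(j)
    (lin %/% radix[j]) %% sizes[j] + 1)
  combo <- matrix(combo, ncol = length(roles),
                  dimnames = list(NULL, roles))
  n <- nrow(combo)

  u_mat <- sapply(roles, function(r) comps[[r]]$u[combo[, r]])
  inter <- numeric(n)
  for (p in seq_len(ncol(pairs)))
    inter <- inter + icoef[p] * u_mat[, pairs[1, p]] * u_mat[, pairs[2, p]]
  inter <- config$interaction_scale * inter / sqrt(ncol(pairs))

  main_sum <- numeric(n)
  for (r in roles) if (!is.null(mains[[r]]))
    main_sum <- main_sum + mains[[r]][combo[, r]]

  shift_vec <- shift[combo[, config$group_role]]
  effect_sum <- config$base_yield + main_sum + inter + unname(shift_vec)
  y_raw <- effect_sum + rnorm(n, sd = config$noise_sd)
  y <- pmin(pmax(y_raw, 0), 100)

  rt <- data.frame(reaction_id = sprintf("rxn_%07d", lin + 1),
                   stringsAsFactors = FALSE)
  for (r in roles)
    rt[[r]] <- rownames(comps[[r]]$values)[combo[, r]]
  rt$yield <- y

  blocks <- lapply(roles, function(r) {
    b <- comps[[r]]$values[combo[, r], , drop = FALSE]
    colnames(b) <- paste(r, comps[[r]]$value_names, sep = ".")
    b
  })
  features <- do.call(cbind, blocks)
  rownames(features) <- rt$reaction_id
  descriptors <- lapply(comps, `[[`, "values")

  cluster_role <- names(which(!vapply(comps, function(cc) is.null(cc$cluster),
                                      logical(1))))
  reaction_cluster <- if (length(cluster_role) == 1)
    comps[[cluster_role]]$cluster[combo[, cluster_role]] else NULL

  dataset <- new_reaction_dataset(rt, features, roles, config$group_role,
                                  descriptors)
  truth <- list(group_shift = shift, shift_dims = sdims, main_effects = mains,
                interaction_pairs = pairs, interaction_coef = icoef,
                shift_weights = w, effect_sum = effect_sum,
                reaction_cluster = reaction_cluster,
                cluster_role = if (length(cluster_role)) cluster_role else NULL,
                noise_sd = config$noise_sd, base_yield = config$base_yield,
                clipped_fraction = mean(y_raw != y))
  list(dataset = dataset, truth = truth)
}
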