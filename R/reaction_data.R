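#' Concatenate per-role descriptors into a reaction encoding
#'
#' A reaction is encoded as the concatenation of the descriptor vectors of its
#' components, one block per role, in a fixed role order. Permuting the role
#' order permutes blocks, never elements within a block.
#'
#' @param components named list mapping role to a numeric descriptor vector.
#' @param role_order character vector of roles fixing the block order.
#' @return numeric vector of length `sum(lengths of the parts)`.
#' @examples
#' encode_reaction(list(A = c(1, 2), B = 3), role_order = c("B", "A"))
#' @export
encode_reaction <- function(components, role_order) {
  missing_roles <- setdiff(role_order, names(components))
  if (length(missing_roles) > 0)
    stop("missing descriptor for role(s): ", paste(missing_roles, collapse = ", "))
  parts <- components[role_order]
  if (any(lengths(parts) == 0)) stop("empty descriptor vector")
  out <- unlist(parts, use.names = FALSE)
  if (!all(is.finite(out))) stop("descriptors must be finite")
  out
}

#' Load a reaction dataset from CSV tables
#'
#' Reads one reaction table (columns `reaction_id`, one column of component
#' ids per role, `yield`) and one descriptor table per role (column
#' `component_id` followed by numeric descriptor columns, header row naming
#' the descriptor dimensions), and builds the concatenated feature matrix.
#' Record order equals reaction-table row order; selection plans and split
#' indices elsewhere refer to this order (1-based).
#'
#' @param reaction_file path to the reaction CSV.
#' @param descriptor_files named list/vector mapping role to its descriptor
#'   CSV path. The order of names fixes the concatenation order.
#' @param group_role the role whose values define tasks/groups.
#' @return an object of class `reaction_dataset` with elements `reactions`
#'   (the reaction table), `features` (N x d numeric matrix), `roles`,
#'   `group_role` and `descriptors` (per-role matrices and dimension names).
#' @export
load_dataset <- function(reaction_file, descriptor_files, group_role) {
  roles <- names(descriptor_files)
  if (is.null(roles) || any(roles == ""))
    stop("descriptor_files must be a named list: role -> path")
  if (!group_role %in% roles)
    stop("group_role '", group_role, "' is not one of the roles")
  rt <- read.csv(reaction_file, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("reaction_id", roles, "yield")
  miss <- setdiff(need, names(rt))
  if (length(miss) > 0)
    stop("reaction table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(rt$reaction_id))
    stop("duplicate reaction_id: ",
         rt$reaction_id[duplicated(rt$reaction_id)][1])
  bad <- which(!is.finite(rt$yield) | rt$yield < 0 | rt$yield > 100)
  if (length(bad) > 0)
    stop("yield outside [0, 100] at row ", bad[1])

  descriptors <- lapply(roles, function(r) {
    df <- read.csv(descriptor_files[[r]], stringsAsFactors = FALSE,
                   check.names = FALSE)
    if (names(df)[1] != "component_id")
      stop("descriptor table for role '", r,
           "' must start with a component_id column")
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    if (!all(is.finite(m)))
      stop("non-finite descriptor values for role '", r, "'")
    rownames(m) <- df$component_id
    m
  })
  names(descriptors) <- roles

  blocks <- lapply(roles, function(r) {
    m <- descriptors[[r]]
    idx <- match(rt[[r]], rownames(m))
    if (anyNA(idx)) {
      unknown <- rt[[r]][which(is.na(idx))[1]]
      stop("unknown component id '", unknown, "' for role '", r, "'")
    }
    b <- m[idx, , drop = FALSE]
    colnames(b) <- paste(r, colnames(m), sep = ".")
    b
  })
  features <- do.call(cbind, blocks)
  rownames(features) <- rt$reaction_id
  new_reaction_dataset(rt, features, roles, group_role, descriptors)
}

new_reaction_dataset <- function(reactions, features, roles, group_role,
                                 descriptors) {
  structure(list(reactions = reactions, features = features, roles = roles,
                 group_role = group_role, descriptors = descriptors),
            class = "reaction_dataset")
}

#' @export
print.reaction_dataset <- function(x, ...) {
  cat("reaction_dataset:", nrow(x$features), "reactions,",
      ncol(x$features), "features\n")
  cat("  roles:", paste(x$roles, collapse = ", "),
      "(grouped by", paste0(x$group_role, ")"), "\n")
  g <- reaction_groups(x)
  cat("  groups:", length(unique(g)), "distinct values of", x$group_role, "\n")
  invisible(x)
}

#' Accessors for reaction datasets
#'
#' @param dataset a `reaction_dataset`.
#' @return `reaction_features()` the N x d feature matrix; `reaction_yields()`
#'   the percent-yield vector; `reaction_groups()` the group (additive) value
#'   of each record; `n_reactions()` the record count.
#' @export
reaction_features <- function(dataset) dataset$features

#' @rdname reaction_features
#' @export
reaction_yields <- function(dataset) dataset$reactions$yield

#' @rdname reaction_features
#' @export
reaction_groups <- function(dataset) dataset$reactions[[dataset$group_role]]

#' @rdname reaction_features
#' @export
n_reactions <- function(dataset) nrow(dataset$features)

#' Columns of the feature matrix belonging to each role
#'
#' @param dataset a `reaction_dataset`.
#' @return named list of integer column indices, one entry per role, jointly
#'   partitioning `1:ncol(reaction_features(dataset))`.
#' @export
role_feature_blocks <- function(dataset) {
  dims <- vapply(dataset$descriptors, ncol, integer(1))
  ends <- cumsum(dims)
  starts <- c(1L, head(ends, -1) + 1L)
  out <- Map(function(s, e) seq.int(s, e), starts, ends)
  names(out) <- dataset$roles
  out
}

#' Leave-reagent-out split of a dataset by group value
#'
#' Draws disjoint training / validation / test sets of *group values* (not
#' records) without replacement; every remaining group becomes a test group,
#' so unseen-reagent evaluation is always possible. With 22 equal-sized groups
#' and `n_train = 4`, `n_val = 1`, train + validation hold 5/22 (about 22.7%)
#' of the records.
#'
#' @param dataset a `reaction_dataset`.
#' @param n_train,n_val number of training / validation groups
#'   (`n_train >= 1`; `n_train + n_val` must be < number of groups).
#' @param seed integer seed; the draw is deterministic given it.
#' @param train_fraction fraction in (0, 1] of training-group records used
#'   (uniform subsample without replacement); shrinks the training set but
#'   never the group structure.
#' @param subsample_seed seed of the within-group subsample draw.
#' @return an object of class `split_spec` with `train_groups`, `val_groups`,
#'   `test_groups`, `train_fraction` and `subsample_seed`.
#' @export
split_by_group <- function(dataset, n_train, n_val, seed = 1L,
                           train_fraction = 1, subsample_seed = seed + 1L) {
  groups <- unique(reaction_groups(dataset))
  stopifnot(n_train >= 1, n_val >= 0, train_fraction > 0, train_fraction <= 1)
  if (n_train + n_val >= length(groups))
    stop("n_train + n_val (", n_train + n_val, ") must be < number of groups (",
         length(groups), "): no test group would remain")
  set.seed(as.integer(seed))
  perm <- sample(groups)
  structure(list(train_groups = perm[seq_len(n_train)],
                 val_groups = if (n_val > 0)
                   perm[n_train + seq_len(n_val)] else character(0),
                 test_groups = perm[-seq_len(n_train + n_val)],
                 train_fraction = train_fraction,
                 subsample_seed = as.integer(subsample_seed)),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat("split_spec:", length(x$train_groups), "train /", length(x$val_groups),
      "val /", length(x$test_groups), "test groups",
      sprintf("(train_fraction = %g)\n", x$train_fraction))
  invisible(x)
}

#' Record indices implied by a split
#'
#' Resolves a group-level [split_by_group()] specification to 1-based record
#' indices. `train` applies the within-group `train_fraction` subsample
#' (seeded by `subsample_seed`); `train_full` ignores it.
#'
#' @param dataset a `reaction_dataset`.
#' @param split a `split_spec`.
#' @return list with integer index vectors `train`, `train_full`, `val`,
#'   `test`.
#' @export
split_indices <- function(dataset, split) {
  g <- reaction_groups(dataset)
  train_full <- which(g %in% split$train_groups)
  train <- train_full
  if (split$train_fraction < 1) {
    m <- max(1L, round(split$train_fraction * length(train_full)))
    set.seed(split$subsample_seed)
    train <- sort(sample(train_full, m))
  }
  list(train = train, train_full = train_full,
       val = which(g %in% split$val_groups),
       test = which(g %in% split$test_groups))
}

#' Write a dataset back to the CSV interchange format
#'
#' Emits the reaction table and one descriptor table per role in the format
#' [load_dataset()] reads, so generated datasets round-trip.
#'
#' @param dataset a `reaction_dataset`.
#' @param dir output directory (created if absent).
#' @return invisibly, the named list of file paths written (element
#'   `reactions` plus one per role).
#' @export
write_dataset_csv <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(reactions = file.path(dir, "reactions.csv"))
  write.csv(dataset$reactions, paths$reactions, row.names = FALSE)
  for (r in dataset$roles) {
    m <- dataset$descriptors[[r]]
    df <- data.frame(component_id = rownames(m), m, check.names = FALSE,
                     row.names = NULL)
    paths[[r]] <- file.path(dir, paste0("descriptors_", r, ".csv"))
    write.csv(df, paths[[r]], row.names = FALSE)
  }
  invisible(paths)
}
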