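test_that("encode_reaction concatenates blocks in role order", {
  comps <- list(A = c(1, 2), B = 3, C = c(4, 5), D = 6)
  expect_equal(encode_reaction(comps, c("A", "B", "C", "D")),
               c(1, 2, 3, 4, 5, 6))
  # permuting the role order permutes blocks, never elements within a block
  expect_equal(encode_reaction(comps, c("B", "A")), c(3, 1, 2))
  # length additivity
  parts <- list(w = rnorm(19), x = rnorm(27), y = rnorm(19), z = rnorm(10))
  expect_length(encode_reaction(parts, names(parts)), 75)
  expect_error(encode_reaction(comps, c("A", "E")), "E")
})

test_that("feature vectors round-trip through their descriptor slices", {
  comps <- list(A = c(1.5, -2), B = c(0.25), C = c(7, 8, 9))
  v <- encode_reaction(comps, c("C", "A", "B"))
  slices <- list(C = v[1:3], A = v[4:5], B = v[6])
  expect_identical(encode_reaction(slices, c("C", "A", "B")), v)
})

test_that("load_dataset builds features and enforces referential integrity", {
  paths <- write_toy_csvs(withr::local_tempdir())
  ds <- load_dataset(paths$reactions, paths$descriptors, group_role = "roleB")
  expect_s3_class(ds, "reaction_dataset")
  expect_equal(n_reactions(ds), 2)
  expect_equal(ncol(reaction_features(ds)), 5)
  # record order equals row order; features are the concatenated descriptors
  expect_equal(unname(reaction_features(ds)[1, ]), c(1, 2, 3, 30, 40))
  expect_equal(unname(reaction_features(ds)[2, ]), c(4, 5, 6, 10, 20))
  expect_equal(reaction_yields(ds), c(12.5, 80))
  # same input loaded twice -> identical datasets
  ds2 <- load_dataset(paths$reactions, paths$descriptors, group_role = "roleB")
  expect_identical(ds, ds2)

  # unknown component id
  bad <- read.csv(paths$reactions, stringsAsFactors = FALSE)
  bad$roleA[2] <- "a9"
  f <- file.path(withr::local_tempdir(), "bad.csv")
  write.csv(bad, f, row.names = FALSE)
  expect_error(load_dataset(f, paths$descriptors, "roleB"), "a9")

  # yield out of range reports the row
  bad2 <- read.csv(paths$reactions, stringsAsFactors = FALSE)
  bad2$yield[2] <- 104
  write.csv(bad2, f, row.names = FALSE)
  expect_error(load_dataset(f, paths$descriptors, "roleB"), "row 2")

  # duplicated reaction ids
  bad3 <- read.csv(paths$reactions, stringsAsFactors = FALSE)
  bad3$reaction_id[2] <- "r1"
  write.csv(bad3, f, row.names = FALSE)
  expect_error(load_dataset(f, paths$descriptors, "roleB"), "duplicate")
})

test_that("generated datasets round-trip through the CSV interchange format", {
  ds <- small_dataset()$dataset
  dir <- withr::local_tempdir()
  paths <- write_dataset_csv(ds, dir)
  re <- load_dataset(paths$reactions,
                     paths[ds$roles], group_role = ds$group_role)
  expect_equal(reaction_features(re), reaction_features(ds))
  expect_equal(reaction_yields(re), reaction_yields(ds))
})

test_that("split_by_group partitions groups and honours the arithmetic", {
  ds <- small_dataset()$dataset
  sp <- split_by_group(ds, 2, 1, seed = 7)
  g <- unique(reaction_groups(ds))
  expect_setequal(c(sp$train_groups, sp$val_groups, sp$test_groups), g)
  expect_length(intersect(sp$train_groups, sp$test_groups), 0)
  # deterministic for a fixed seed
  expect_identical(sp, split_by_group(ds, 2, 1, seed = 7))
  # indices partition all records at train_fraction = 1
  idx <- split_indices(ds, sp)
  expect_setequal(c(idx$train, idx$val, idx$test), seq_len(n_reactions(ds)))
  expect_length(intersect(idx$train, idx$test), 0)
  # no test group left -> error
  expect_error(split_by_group(ds, 7, 1, seed = 1), "test group")
})

test_that("22 equal groups split 4/1/17 put 22.7% of records in train+val", {
  cfg <- synth_config(roles = c(aryl_halide = 3L, ligand = 2L, base = 2L,
                                additive = 22L),
                      descriptor_dim = 4L, n_informative = 2L, seed = 5)
  ds <- gen_dataset(cfg)$dataset
  sp <- split_by_group(ds, 4, 1, seed = 11)
  idx <- split_indices(ds, sp)
  frac <- (length(idx$train) + length(idx$val)) / n_reactions(ds)
  expect_equal(frac, 5 / 22)
  expect_equal(round(100 * frac, 1), 22.7)
})

test_that("train_fraction subsamples training groups only, reproducibly", {
  ds <- small_dataset()$dataset
  sp <- split_by_group(ds, 2, 1, seed = 7, train_fraction = 0.25,
                       subsample_seed = 99)
  idx <- split_indices(ds, sp)
  expect_equal(length(idx$train), round(0.25 * length(idx$train_full)))
  expect_true(all(idx$train %in% idx$train_full))
  expect_identical(idx$train, split_indices(ds, sp)$train)
  expect_identical(idx$val, split_indices(ds, split_by_group(
    ds, 2, 1, seed = 7))$val)
})
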