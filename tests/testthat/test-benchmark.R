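# Small, fast harness runs: 8 groups (2 train / 1 val / 5 test), 288
# reactions, 15 trees. These check the protocol contracts, not statistical
# performance (that lives in the acceptance suite).
bench_fixtures <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$ds)) {
      cache$ds <- small_dataset(3)$dataset
      cache$sp <- split_by_group(cache$ds, 2, 1, seed = 5)
      cache$fc <- forest_config(n_trees = 15L, seed = 1)
      cache$mc <- meta_config(meta_iterations = 10L, support_size = 10L)
      cache$ec <- embed_config(iterations = 60L)
    }
    as.list(cache)
  }
})

test_that("the few-shot benchmark returns pooled and per-group metrics", {
  fx <- bench_fixtures()
  bm <- run_fewshot_benchmark(fx$ds, fx$sp, "metarf", n_finetune = 4,
                              seeds = 1:2, forest_config = fx$fc,
                              meta_config = fx$mc, embed_config = fx$ec)
  expect_s3_class(bm, "benchmark_result")
  expect_equal(nrow(bm$summary), 2)
  expect_true(all(c("r2", "rmse", "mae", "rmse_pre") %in% names(bm$summary)))
  gdf <- bm$per_seed[[1]]$groups
  expect_setequal(gdf$group, as.character(fx$sp$test_groups))
  # query sets exclude the supports
  expect_equal(gdf$n_query,
               as.vector(table(reaction_groups(fx$ds))[gdf$group]) - 4)
  expect_true(all(is.finite(bm$summary$rmse)))
})

test_that("benchmark runs are reproducible from their seeds", {
  fx <- bench_fixtures()
  b1 <- run_fewshot_benchmark(fx$ds, fx$sp, "metarf", n_finetune = 3,
                              seeds = 7, forest_config = fx$fc,
                              meta_config = fx$mc, embed_config = fx$ec)
  b2 <- run_fewshot_benchmark(fx$ds, fx$sp, "metarf", n_finetune = 3,
                              seeds = 7, forest_config = fx$fc,
                              meta_config = fx$mc, embed_config = fx$ec)
  expect_identical(b1$summary, b2$summary)
})

test_that("zero-shot evaluation degenerates to the meta-trained head", {
  fx <- bench_fixtures()
  bm <- run_fewshot_benchmark(fx$ds, fx$sp, "metarf", n_finetune = 0,
                              seeds = 1, forest_config = fx$fc,
                              meta_config = fx$mc, embed_config = fx$ec)
  expect_equal(bm$summary$rmse, bm$summary$rmse_pre)
})

test_that("the rf baseline equals ensemble-mean forest predictions", {
  fx <- bench_fixtures()
  bm <- run_fewshot_benchmark(fx$ds, fx$sp, "rf_baseline", n_finetune = 3,
                              seeds = 2, forest_config = fx$fc,
                              meta_config = fx$mc, embed_config = fx$ec)
  # reconstruct the enlarged forest from the recorded supports and seeds
  idx <- split_indices(fx$ds, fx$sp)
  sup <- unlist(bm$per_seed[[1]]$reps[[1]]$supports, use.names = FALSE)
  fc <- fx$fc
  fc$seed <- metayield:::derive_seed(2, 5L)
  x <- reaction_features(fx$ds)
  y <- reaction_yields(fx$ds)
  enlarged <- c(idx$train, sup)
  fb <- fit_forest(x[enlarged, , drop = FALSE], y[enlarged], fc)
  gv <- as.character(fx$sp$test_groups[1])
  cand <- which(reaction_groups(fx$ds) == gv)
  q <- setdiff(cand, bm$per_seed[[1]]$reps[[1]]$supports[[gv]])
  want <- rowMeans(tree_transform(fb, x[q, , drop = FALSE]))
  got_rmse <- bm$per_seed[[1]]$groups$rmse[
    bm$per_seed[[1]]$groups$group == gv]
  expect_equal(got_rmse, rmse(y[q], want))
})

test_that("pooled RMSE^2 is the size-weighted mean of per-group RMSE^2", {
  fx <- bench_fixtures()
  bm <- run_fewshot_benchmark(fx$ds, fx$sp, "metarf", n_finetune = 3,
                              seeds = 4, forest_config = fx$fc,
                              meta_config = fx$mc, embed_config = fx$ec)
  g <- bm$per_seed[[1]]$groups
  pooled <- bm$per_seed[[1]]$pooled[["rmse"]]
  expect_equal(pooled^2, sum(g$n_query * g$rmse^2) / sum(g$n_query))
})

test_that("groups smaller than n_finetune + 1 are skipped with a warning", {
  fx <- bench_fixtures()
  expect_warning(
    bm <- run_fewshot_benchmark(fx$ds, fx$sp, "metarf",
                                n_finetune = 35,  # groups have 36 records
                                seeds = 1, forest_config = fx$fc,
                                meta_config = fx$mc, embed_config = fx$ec,
                                sampling = "random"),
    NA)  # 36 >= 36: no skip at the boundary
  expect_error(
    suppressWarnings(
      run_fewshot_benchmark(fx$ds, fx$sp, "metarf", n_finetune = 36,
                            seeds = 1, forest_config = fx$fc,
                            meta_config = fx$mc, embed_config = fx$ec,
                            sampling = "random")),
    "no evaluable")
})

test_that("every ablation variant runs and reports all three metrics", {
  fx <- bench_fixtures()
  for (v in c("metarf_random_sampling", "maml_on_raw_features",
              "transfer_head", "transfer_head_random_sampling")) {
    ab <- run_ablation(fx$ds, fx$sp, v, n_finetune = 3, seeds = 1,
                       forest_config = fx$fc, meta_config = fx$mc,
                       embed_config = fx$ec, sampling_reps = 2)
    expect_s3_class(ab, "benchmark_result")
    expect_true(all(is.finite(unlist(
      ab$summary[, c("r2", "rmse", "mae")]))), info = v)
  }
  expect_error(run_ablation(fx$ds, fx$sp, "bogus"), "unknown ablation")
})

test_that("random-sampling repetitions are averaged into pooled metrics", {
  fx <- bench_fixtures()
  ab <- run_ablation(fx$ds, fx$sp, "metarf_random_sampling", n_finetune = 3,
                     seeds = 1, forest_config = fx$fc, meta_config = fx$mc,
                     embed_config = fx$ec, sampling_reps = 3)
  reps <- ab$per_seed[[1]]$reps
  expect_length(reps, 3)
  expect_equal(ab$per_seed[[1]]$pooled[["rmse"]],
               mean(vapply(reps, function(r) r$pooled[["rmse"]], numeric(1))))
  # different repetitions draw different supports
  expect_false(identical(reps[[1]]$supports, reps[[2]]$supports))
})
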