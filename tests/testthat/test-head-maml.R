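make_toy <- function(M = 3, n = 6, seed = 1, hidden = c(5L, 4L)) {
  set.seed(seed)
  head <- init_head(M, hidden, seed = seed)
  # move the zero output layer off zero so all gradients are generic
  head$layers[[length(head$layers)]]$W[] <- rnorm(hidden[length(hidden)],
                                                  sd = 0.5)
  head$layers[[length(head$layers)]]$b[] <- 0.1
  list(head = head,
       x = matrix(runif(n * M, -1, 1), n),
       y = runif(n, -1, 1))
}

test_that("task_loss is the mean of squared errors", {
  toy <- make_toy()
  p <- head_predict(toy$head, toy$x)
  expect_equal(task_loss(toy$head, toy$x, p), 0)
  # hand example via a constant (all-zero) head: predictions are the bias
  h0 <- init_head(2, integer(0))
  h0$layers[[1]]$b <- 0
  expect_equal(head_predict(h0, matrix(c(1, 2, 3, 4), 2)), c(0, 0))
  expect_equal(task_loss(h0, matrix(c(1, 2, 3, 4), 2), c(-1, -2)),
               (1 + 4) / 2)
  expect_error(task_loss(toy$head, toy$x[0, , drop = FALSE], numeric(0)),
               "at least one")
})

test_that("backprop gradient matches central finite differences", {
  toy <- make_toy()
  template <- toy$head$layers
  fun <- function(th) {
    h <- toy$head
    h$layers <- metayield:::unflatten_params(th, template)
    task_loss(h, toy$x, toy$y)
  }
  theta <- metayield:::flatten_params(template)
  analytic <- metayield:::flatten_params(
    metayield:::head_gradient(template, toy$x, toy$y))
  numeric_g <- fd_grad(fun, theta)
  expect_lt(max(abs(analytic - numeric_g)) / max(abs(numeric_g)), 1e-6)
})

test_that("inner_update takes exactly one analytic gradient step", {
  toy <- make_toy()
  # alpha = 0 is the identity
  expect_equal(inner_update(toy$head, toy$x, toy$y, 0)$layers,
               toy$head$layers)
  # scalar analytic case: constant head f = b, one pair with target 3,
  # b = 1, alpha = 0.1 -> b' = 1 - 0.1 * 2 * (1 - 3) = 1.4
  h0 <- init_head(1, c(3L))          # zero output layer: f(x) = b_out
  h0$layers[[2]]$b <- 1
  upd <- inner_update(h0, matrix(0.5), 3, 0.1)
  expect_equal(upd$layers[[2]]$b, 1.4)
  # the input head is never mutated
  before <- toy$head$layers
  invisible(inner_update(toy$head, toy$x, toy$y, 0.05))
  expect_identical(toy$head$layers, before)
  # fine_tune is definitionally the same single step
  expect_equal(fine_tune(toy$head, toy$x, toy$y, 0.05)$layers,
               inner_update(toy$head, toy$x, toy$y, 0.05)$layers)
})

test_that("second-order meta-gradient matches finite differences of the
           post-inner-step query loss", {
  toy <- make_toy(M = 4, n = 10, seed = 3)
  sup <- list(x = toy$x[1:5, ], y = toy$y[1:5])
  qry <- list(x = toy$x[6:10, ], y = toy$y[6:10])
  alpha <- 0.05
  template <- toy$head$layers
  fun <- function(th) {
    h <- toy$head
    h$layers <- metayield:::unflatten_params(th, template)
    h2 <- inner_update(h, sup$x, sup$y, alpha)
    task_loss(h2, qry$x, qry$y)
  }
  theta <- metayield:::flatten_params(template)
  analytic <- metayield:::flatten_params(
    metayield:::outer_gradient(toy$head, sup$x, sup$y, qry$x, qry$y, alpha,
                               second_order = TRUE))
  numeric_g <- fd_grad(fun, theta, h = 1e-5)
  rel <- max(abs(analytic - numeric_g)) / max(abs(numeric_g))
  expect_lt(rel, 1e-4)
  # the first-order approximation differs (the Hessian term is real)
  fo <- metayield:::flatten_params(
    metayield:::outer_gradient(toy$head, sup$x, sup$y, qry$x, qry$y, alpha,
                               second_order = FALSE))
  expect_gt(max(abs(fo - analytic)), 1e-8)
})

test_that("sample_task splits one group into disjoint support and query", {
  pool <- list(g1 = list(x = matrix(rnorm(16), 8), y = rnorm(8)))
  task <- sample_task(pool, K = 5, seed = 1)
  expect_equal(task$group_value, "g1")
  expect_length(task$support$y, 5)
  expect_length(task$query$y, 3)
  joined <- rbind(task$support$x, task$query$x)
  expect_equal(joined[order(joined[, 1]), ], pool$g1$x[order(pool$g1$x[, 1]), ])
  # deterministic per seed
  t2 <- sample_task(pool, K = 5, seed = 1)
  expect_identical(task, t2)
  # groups at or below K pairs are excluded
  pool$tiny <- list(x = matrix(rnorm(4), 2), y = rnorm(2))
  expect_error(sample_task(list(tiny = pool$tiny), K = 5), "no group")
})

test_that("eligible groups are drawn approximately uniformly", {
  pool <- list(a = list(x = matrix(rnorm(20), 10), y = rnorm(10)),
               b = list(x = matrix(rnorm(20), 10), y = rnorm(10)))
  picks <- vapply(1:1000, function(s) sample_task(pool, 4, seed = s)$group_value,
                  character(1))
  frac_a <- mean(picks == "a")
  expect_gte(frac_a, 0.4)
  expect_lte(frac_a, 0.6)
})

test_that("meta_train with zero iterations returns the seeded initialization", {
  pool <- list(g = list(x = matrix(runif(60, 0, 100), 20), y = runif(20, 0, 100)))
  cfg <- meta_config(meta_iterations = 0, seed = 5, init = "random",
                     standardize = FALSE)
  h <- meta_train(pool, 3, cfg)
  set.seed(5)
  ref <- init_head(3, cfg$hidden)
  expect_equal(h$layers, ref$layers)
  # same contract for the calibrated default initialization
  cfg2 <- meta_config(meta_iterations = 0, seed = 5)
  expect_equal(meta_train(pool, 3, cfg2)$layers,
               meta_train(pool, 3, cfg2)$layers)
})

test_that("meta_train trajectories are reproducible bit for bit", {
  set.seed(77)
  pool <- list(g1 = list(x = matrix(runif(300, 0, 100), 50), y = runif(50, 0, 100)),
               g2 = list(x = matrix(runif(300, 0, 100), 50), y = runif(50, 0, 100)))
  cfg <- meta_config(meta_iterations = 15, support_size = 10, seed = 2)
  h1 <- meta_train(pool, 6, cfg)
  h2 <- meta_train(pool, 6, cfg)
  expect_identical(h1$layers, h2$layers)
  expect_identical(attr(h1, "objective_log"), attr(h2, "objective_log"))
})

test_that("the outer objective decreases on a convex linear-head problem", {
  # linear head + frozen tasks: the post-inner-step query loss is a convex
  # quadratic in theta, so small-step descent must not increase it
  set.seed(4)
  M <- 3
  tasks <- lapply(1:3, function(i) {
    x <- matrix(rnorm(8 * M), 8)
    beta <- rnorm(M)
    y <- as.vector(x %*% beta) + rnorm(8, sd = 0.1)
    list(sup = list(x = x[1:4, ], y = y[1:4]),
         qry = list(x = x[5:8, ], y = y[5:8]))
  })
  head <- init_head(M, integer(0), seed = 1)
  alpha <- 0.01
  outer_obj <- function(h) sum(vapply(tasks, function(t) {
    task_loss(inner_update(h, t$sup$x, t$sup$y, alpha), t$qry$x, t$qry$y)
  }, numeric(1)))
  template <- head$layers
  theta <- metayield:::flatten_params(template)
  objs <- numeric(11)
  objs[1] <- outer_obj(head)
  for (it in 1:10) {
    g <- Reduce(`+`, lapply(tasks, function(t)
      metayield:::flatten_params(metayield:::outer_gradient(
        head, t$sup$x, t$sup$y, t$qry$x, t$qry$y, alpha, TRUE))))
    theta <- theta - 1e-3 * g
    head$layers <- metayield:::unflatten_params(theta, template)
    objs[it + 1] <- outer_obj(head)
  }
  expect_true(all(diff(objs) <= 1e-10))
})

test_that("predict_yield composes transform and head, with optional clip", {
  ds <- small_dataset()$dataset
  x <- reaction_features(ds)[1:40, ]
  y <- reaction_yields(ds)[1:40]
  f <- fit_forest(x, y, forest_config(n_trees = 8, seed = 1))
  h <- init_head(8, seed = 2)
  h$layers[[3]]$b <- 150            # constant head beyond the yield range
  p <- predict_yield(f, h, x)
  expect_equal(unname(p), rep(150, 40))
  expect_true(all(predict_yield(f, h, x, clip = TRUE) <= 100))
  expect_true(all(is.finite(predict_yield(f, init_head(8, seed = 3), x))))
  expect_error(predict_yield(f, h, x[, 1:3]), "mismatch")
})

test_that("meta-training never mutates the fitted forest", {
  dsd <- small_dataset()
  ds <- dsd$dataset
  idx <- 1:120
  f <- fit_forest(reaction_features(ds)[idx, ], reaction_yields(ds)[idx],
                  forest_config(n_trees = 10, seed = 5))
  before <- serialize_forest(f)
  pool <- make_task_pool(ds, idx, f)
  h <- meta_train(pool, 10, meta_config(meta_iterations = 10,
                                        support_size = 5, seed = 1))
  invisible(fine_tune(h, pool[[1]]$x[1:3, ], pool[[1]]$y[1:3], 1e-4))
  expect_identical(serialize_forest(f), before)
})
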