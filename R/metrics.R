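#' Regression metrics on the percent-yield scale
#'
#' Standard definitions: `r2 = 1 - SS_res / SS_tot` with `SS_tot` about the
#' mean of `y_true`; `rmse` the root mean squared error; `mae` the mean
#' absolute error. All operate on the percent scale yields are stored in.
#'
#' @param y_true,y_pred numeric vectors of equal nonzero length.
#' @return scalar; `r2 <= 1`, `rmse >= 0`, `mae >= 0`.
#' @export
r2 <- function(y_true, y_pred) {
  check_metric_input(y_true, y_pred)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("r2 undefined: y_true is constant")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' @rdname r2
#' @export
rmse <- function(y_true, y_pred) {
  check_metric_input(y_true, y_pred)
  sqrt(mean((y_true - y_pred)^2))
}

#' @rdname r2
#' @export
mae <- function(y_true, y_pred) {
  check_metric_input(y_true, y_pred)
  mean(abs(y_true - y_pred))
}

check_metric_input <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal nonzero length")
  invisible(NULL)
}

#' True yields of the predicted-best k reactions
#'
#' Ranks reactions by predicted yield (ties broken by lower index), takes the
#' top `k`, and reports mean and standard deviation of their *true* yields —
#' the "did the model find the high-yield reactions" summary. `mode =
#' "ideal"` ranks by the true yields themselves (the oracle ceiling);
#' `mode = "random"` averages mean and sd over `n_draws` seeded uniform
#' draws of k reactions.
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @param k number of reactions selected (`k <= length(y_true)`).
#' @param mode `"predicted"`, `"ideal"` or `"random"`.
#' @param n_draws number of draws for `mode = "random"`.
#' @param seed seed for `mode = "random"`.
#' @return list with `mean`, `sd` and (for non-random modes) `indices`.
#' @export
topk_selection <- function(y_true, y_pred, k, mode = c("predicted", "ideal",
                                                       "random"),
                           n_draws = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  if (k > length(y_true)) stop("k exceeds the number of reactions")
  if (mode == "random") {
    set.seed(as.integer(seed))
    draws <- replicate(n_draws, {
      idx <- sample(length(y_true), k)
      c(mean(y_true[idx]), sd(y_true[idx]))
    })
    return(list(mean = mean(draws[1, ]), sd = mean(draws[2, ]),
                indices = NULL))
  }
  score <- if (mode == "ideal") y_true else y_pred
  idx <- order(score, decreasing = TRUE)[seq_len(k)]
  list(mean = mean(y_true[idx]), sd = sd(y_true[idx]), indices = idx)
}
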