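#' Initialize the attention head
#'
#' The head is a small feed-forward regressor `f_theta` mapping a tree-output
#' vector (length `input_dim = M`) to a scalar yield: by default two hidden
#' layers of width 40 with rectified-linear activations and a linear output.
#' Hidden weights use fan-in-scaled normal initialization (`sd =
#' 1/sqrt(fan_in)`), biases start at zero, and the output layer starts at
#' exactly zero: initial predictions are 0, and the size of the first inner
#' gradient step is then governed by the percent-scale activations, which is
#' what calibrates the published inner learning rate. `hidden = integer(0)`
#' gives a purely linear head (useful because its meta-objective is convex).
#'
#' @param input_dim input size (number of trees, or raw feature dimension in
#'   the forest-free ablation).
#' @param hidden integer vector of hidden widths.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param x_center,x_scale optional per-column input standardization applied
#'   before the first layer (off — `NULL` — by default; tree outputs enter
#'   on the raw percent scale).
#' @return an object of class `attention_head`.
#' @export
init_head <- function(input_dim, hidden = c(40L, 40L), seed = NULL,
                      x_center = NULL, x_scale = NULL) {
  stopifnot(input_dim >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  dims <- c(input_dim, hidden, 1L)
  n_layer <- length(dims) - 1L
  layers <- lapply(seq_len(n_layer), function(l) {
    fan_in <- dims[l]
    sd_l <- if (l == n_layer) 0 else 1 / sqrt(fan_in)
    W <- if (sd_l == 0)
      matrix(0, dims[l + 1L], fan_in)
    else matrix(rnorm(dims[l + 1L] * fan_in, sd = sd_l), dims[l + 1L], fan_in)
    list(W = W, b = numeric(dims[l + 1L]))
  })
  structure(list(layers = layers, input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 x_center = x_center, x_scale = x_scale),
            class = "attention_head")
}

#' Initialize the head at the ensemble-mean predictor
#'
#' Builds a head whose first unit carries the uniform tree average exactly
#' (an identity "bypass" through every layer), so that before any training
#' the head predicts what the plain random forest predicts. The remaining
#' units start with small random weights and a zero output layer, giving
#' meta-learning capacity to depart from uniform attention. Because the
#' bypass activations live on the percent scale (typical magnitude the mean
#' yield), the gain of one inner gradient step through the bypass is about
#' `2 * inner_lr * mean_yield^2` — order one at the published inner rate —
#' which is what makes single-step few-shot adaptation effective.
#'
#' @param input_dim number of trees `M`.
#' @param hidden hidden widths (any depth, including `integer(0)`).
#' @param x_center,x_scale per-column standardization applied to inputs
#'   (`NULL` for raw inputs).
#' @param seed optional seed for the random capacity.
#' @param kappa scaling of the constant unit (activation `kappa * c0`,
#'   output weight `1 / kappa`); leaves initial predictions unchanged but
#'   tunes the inner-step gain. [meta_train()] calibrates it automatically
#'   so that one inner step transfers a unit support offset approximately
#'   one-to-one to the query predictions.
#' @return an `attention_head` whose initial predictions equal the uniform
#'   column mean of its input.
#' @export
init_ensemble_head <- function(input_dim, hidden = c(40L, 40L),
                               x_center = NULL, x_scale = NULL, seed = NULL,
                               kappa = 1) {
  head <- init_head(input_dim, hidden, seed = seed,
                    x_center = x_center, x_scale = x_scale)
  ctr <- x_center %||% numeric(input_dim)
  scl <- x_scale %||% rep(1, input_dim)
  v <- scl / input_dim          # m(x) = c0 + sum_j scl_j z_j / M
  c0 <- mean(ctr)
  L <- length(head$layers)
  if (L == 1L) {                # linear head: exact representation
    head$layers[[1]]$W[1, ] <- v
    head$layers[[1]]$b[1] <- c0
    return(head)
  }
  if (length(head$layers[[1]]$b) < 3L)
    stop("ensemble-mean initialization needs hidden width >= 3")
  # three bypass units: relu(q) and relu(-q) carry the centered deviation
  # q = m(x) - c0 exactly (relu(q) - relu(-q) = q), and a constant unit at
  # the percent scale c0 both restores the level and gives the inner step
  # its additive, percent-calibrated gain
  head$layers[[1]]$W[1, ] <- v
  head$layers[[1]]$W[2, ] <- -v
  head$layers[[1]]$W[3, ] <- 0
  head$layers[[1]]$b[1:3] <- c(0, 0, kappa * c0)
  if (L > 2L) for (l in 2:(L - 1L)) {
    head$layers[[l]]$W[1:3, ] <- 0
    head$layers[[l]]$W[cbind(1:3, 1:3)] <- 1  # identity carry-through
    head$layers[[l]]$W[-(1:3), 1:3] <- 0      # keep out of random units
  }
  head$layers[[L]]$W[] <- 0
  head$layers[[L]]$W[1, 1:3] <- c(1, -1, 1 / kappa)
  head
}

# Measured gain of one inner step: raise all support targets by one unit,
# take the step, report the mean movement of the query predictions.
inner_step_gain <- function(head, support_x, query_x, alpha) {
  ys <- head_predict(head, support_x) + 1
  h2 <- inner_update(head, support_x, ys, alpha)
  mean(head_predict(h2, query_x) - head_predict(head, query_x))
}

# apply the head's (optional) input standardization
head_input <- function(head, x) {
  x <- matrix(as.numeric(x), ncol = head$input_dim)
  if (!is.null(head$x_center))
    x <- sweep(x, 2, head$x_center)
  if (!is.null(head$x_scale))
    x <- sweep(x, 2, head$x_scale, "/")
  x
}

#' @export
print.attention_head <- function(x, ...) {
  cat("attention_head:", x$input_dim, "->",
      paste(c(x$hidden, 1L), collapse = " -> "),
      sprintf("(%d parameters)\n", length(flatten_params(x$layers))))
  invisible(x)
}

# forward pass caching pre-activations; works for real and complex parameters
# (complex is used for exact Hessian-vector products via the complex-step
# derivative of the gradient)
head_forward_pass <- function(layers, X) {
  L <- length(layers)
  acts <- vector("list", L + 1L)
  zs <- vector("list", L)
  acts[[1L]] <- X
  A <- X
  for (l in seq_len(L)) {
    Z <- A %*% t(layers[[l]]$W) +
      matrix(layers[[l]]$b, nrow(A), length(layers[[l]]$b), byrow = TRUE)
    A <- if (l < L) Z * (Re(Z) > 0) else Z
    zs[[l]] <- Z
    acts[[l + 1L]] <- A
  }
  list(yhat = A[, 1L], zs = zs, acts = acts)
}

#' Evaluate the head on tree-output vectors
#'
#' @param head an `attention_head`.
#' @param x n x input_dim matrix of tree-output (or raw feature) vectors.
#' @return numeric vector of n predictions.
#' @export
head_predict <- function(head, x) {
  head_forward_pass(head$layers, head_input(head, x))$yhat
}

#' Mean-squared task loss
#'
#' The loss of a task is the mean over its (x', y) pairs of the squared error
#' `(f_theta(x') - y)^2`.
#'
#' @param head an `attention_head`.
#' @param x n x input_dim matrix of inputs.
#' @param y length-n target vector (percent yields).
#' @return non-negative scalar.
#' @export
task_loss <- function(head, x, y) {
  if (length(y) == 0) stop("task_loss needs at least one pair")
  mean((head_predict(head, x) - y)^2)
}

# gradient of the mean-squared loss w.r.t. all layer parameters (backprop);
# complex-safe: masks read only the real part
head_gradient <- function(layers, X, y) {
  n <- length(y)
  fp <- head_forward_pass(layers, X)
  delta <- matrix(2 * (fp$yhat - y) / n, ncol = 1L)
  L <- length(layers)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = t(delta) %*% fp$acts[[l]], b = colSums(delta))
    if (l > 1L)
      delta <- (delta %*% layers[[l]]$W) * (Re(fp$zs[[l - 1L]]) > 0)
  }
  grads
}

flatten_params <- function(layers)
  unlist(lapply(layers, function(l) c(as.vector(l$W), l$b)), use.names = FALSE)

unflatten_params <- function(v, template) {
  pos <- 0L
  lapply(template, function(l) {
    nw <- length(l$W); nb <- length(l$b)
    W <- matrix(v[pos + seq_len(nw)], nrow(l$W), ncol(l$W))
    b <- v[pos + nw + seq_len(nb)]
    pos <<- pos + nw + nb
    list(W = W, b = b)
  })
}

# theta + s * g, layer-wise
params_axpy <- function(layers, g, s) {
  Map(function(l, gl) list(W = l$W + s * gl$W, b = l$b + s * gl$b), layers, g)
}

#' One inner gradient-descent step
#'
#' Returns a new head with `theta' = theta - alpha * grad task_loss(theta)`
#' computed on the support pairs; exactly one step, the input head is left
#' unmodified. This is both the inner update of meta-training and the
#' few-shot fine-tune update.
#'
#' @param head an `attention_head`.
#' @param x,y support inputs and targets (non-empty).
#' @param alpha step size (>= 0).
#' @return the updated `attention_head`.
#' @export
inner_update <- function(head, x, y, alpha) {
  if (length(y) == 0) stop("support set is empty")
  stopifnot(alpha >= 0)
  x <- head_input(head, x)
  g <- head_gradient(head$layers, x, y)
  if (!all(vapply(g, function(l) all(is.finite(l$W)) && all(is.finite(l$b)),
                  logical(1))))
    stop("non-finite gradient in inner update")
  head$layers <- params_axpy(head$layers, g, -alpha)
  head
}

#' Few-shot fine-tuning
#'
#' One gradient step from the meta-trained initialization on the support
#' reactions of a new (test) group: `theta_fewshot = theta_meta -
#' alpha * grad L_support(theta_meta)`. Identical to [inner_update()].
#'
#' @inheritParams inner_update
#' @return the adapted `attention_head`.
#' @export
fine_tune <- function(head, x, y, alpha) inner_update(head, x, y, alpha)

# Hessian(support loss)-vector product at theta, exact to machine precision:
# complex-step derivative of the gradient in direction v (the network is
# piecewise analytic; masks depend only on Re(z)).
head_hvp <- function(layers, X, y, v_layers, h = 1e-20) {
  theta_c <- Map(function(l, vl)
    list(W = l$W + (1i * h) * vl$W, b = l$b + (1i * h) * vl$b),
    layers, v_layers)
  Xc <- X + 0i
  g_c <- head_gradient(theta_c, Xc, y)
  lapply(g_c, function(l) list(W = Im(l$W) / h, b = Im(l$b) / h))
}

# outer (meta) gradient for one task: grad_theta L_query(theta - a g_support).
# second order: (I - a H_support) g_query via one HVP; first order drops the
# Hessian term.
outer_gradient <- function(head, support_x, support_y, query_x, query_y,
                           alpha, second_order = TRUE) {
  support_x <- head_input(head, support_x)
  query_x <- head_input(head, query_x)
  g_s <- head_gradient(head$layers, support_x, support_y)
  theta_p <- params_axpy(head$layers, g_s, -alpha)
  g_q <- head_gradient(theta_p, query_x, query_y)
  if (!second_order || alpha == 0) return(g_q)
  hv <- head_hvp(head$layers, support_x, support_y, g_q)
  Map(function(gq, h) list(W = gq$W - alpha * h$W, b = gq$b - alpha * h$b),
      g_q, hv)
}

#' Attention weights over trees
#'
#' The head itself is the attention mechanism; as a readable summary this
#' reports, per input (tree), the L2 norm of its first-layer weight column —
#' how strongly each tree's output enters the head.
#'
#' @param head an `attention_head`.
#' @return numeric vector of length `input_dim`.
#' @export
attention_weights <- function(head) {
  w <- sqrt(colSums(head$layers[[1L]]$W^2))
  names(w) <- paste0("tree", seq_along(w))
  w
}
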