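#' @name net
#' @title Multilayer perceptron emotion-intensity regressor
#'
#' @description
#' A from-scratch MLP mapping a window's feature vector to the five
#' emotion intensities. Forward pass: induced local field
#' v_j = sum_i w_ji x_i + b_j, squashed by a sigmoid (slope `a`) or ReLU in
#' the hidden layers; the output layer is sigmoid in regression mode
#' (intensities in (0, 1)) or softmax in classification mode. Training
#' minimizes the instantaneous error energy xi = 1/2 eps^2 summed over the
#' five output neurons, with the output delta eps * y (1 - y) (sigmoid
#' derivative; ReLU subgradient in ReLU mode), hidden deltas by the
#' standard backpropagation chain, and either the delta rule with momentum
#' (`"sgd"`: dw = alpha dw_prev + eta delta y_presyn) or Adam on the same
#' gradients.
NULL

#' Network specification
#'
#' @param input input width (number of features).
#' @param hidden integer vector of hidden layer sizes, e.g. `c(10, 10)`.
#' @param output output width; 5 for this analysis.
#' @param activation hidden activation: `"sigmoid"` or `"relu"`.
#' @param sigmoid_slope slope `a >= 1` of the sigmoid.
#' @param output_mode `"regression"` (sigmoid outputs) or
#'   `"classification"` (softmax).
#' @param optimizer `"sgd"` (delta rule with momentum) or `"adam"`.
#' @param lr learning rate eta in `[0, 1]`.
#' @param momentum momentum alpha in `[0, 1]` (sgd only).
#' @param epochs training epochs (default 6000).
#' @param seed weight-initialization seed.
#' @return a `network_spec` list.
#' @export
network_spec <- function(input, hidden = c(10, 10), output = 5L,
                         activation = c("sigmoid", "relu"),
                         sigmoid_slope = 1,
                         output_mode = c("regression", "classification"),
                         optimizer = c("sgd", "adam"),
                         lr = 0.1, momentum = 0.9, epochs = 6000L,
                         seed = 1L) {
  activation <- match.arg(activation)
  output_mode <- match.arg(output_mode)
  optimizer <- match.arg(optimizer)
  if (input < 1L || any(hidden < 1L) || output < 1L)
    stop("layer widths must be >= 1")
  if (lr < 0 || lr > 1) stop("`lr` must be in [0, 1]")
  if (momentum < 0 || momentum > 1) stop("`momentum` must be in [0, 1]")
  if (epochs < 1L) stop("`epochs` must be >= 1")
  if (sigmoid_slope < 1) stop("`sigmoid_slope` must be >= 1")
  structure(list(input = as.integer(input), hidden = as.integer(hidden),
                 output = as.integer(output), activation = activation,
                 sigmoid_slope = sigmoid_slope, output_mode = output_mode,
                 optimizer = optimizer, lr = lr, momentum = momentum,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "network_spec")
}

#' Initialize an MLP from a specification
#'
#' Weights are drawn uniformly with Glorot scaling
#' (limit sqrt(6 / (fan_in + fan_out))), biases start at zero;
#' deterministic given `spec$seed`.
#'
#' @param spec a [network_spec()].
#' @return an `mlp_model`: list with `weights` (list of out x in
#'   matrices), `biases`, `spec`, and an empty training `trace`.
#' @export
init_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  sizes <- c(spec$input, spec$hidden, spec$output)
  with_seed(spec$seed, {
    weights <- list(); biases <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
      lim <- sqrt(6 / (fan_in + fan_out))
      weights[[l]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim),
                             nrow = fan_out, ncol = fan_in)
      biases[[l]] <- rep(0, fan_out)
    }
    structure(list(weights = weights, biases = biases, spec = spec,
                   feature_names = NULL, trace = numeric(0)),
              class = "mlp_model")
  })
}

#' @export
print.mlp_model <- function(x, ...) {
  sizes <- c(x$spec$input, x$spec$hidden, x$spec$output)
  cat(sprintf("<mlp_model> %s | %s hidden, %s output (%s), optimizer %s\n",
              paste(sizes, collapse = "-"), x$spec$activation,
              if (x$spec$output_mode == "regression") "sigmoid" else "softmax",
              x$spec$output_mode, x$spec$optimizer))
  if (length(x$trace))
    cat(sprintf("  trained %d epochs, final mean error energy %.3g\n",
                length(x$trace), x$trace[length(x$trace)]))
  invisible(x)
}

.sigmoid <- function(v, a = 1) 1 / (1 + exp(-a * v))

.activate <- function(v, activation, a) {
  if (activation == "sigmoid") .sigmoid(v, a) else pmax(v, 0)
}

# derivative wrt v, expressed from the activation y (and v for relu)
.activate_deriv <- function(y, v, activation, a) {
  if (activation == "sigmoid") a * y * (1 - y)
  else (v > 0) * 1           # subgradient 0 at v = 0
}

.softmax_rows <- function(v) {
  m <- apply(v, 1L, max)
  e <- exp(v - m)
  e / rowSums(e)
}

# forward pass keeping per-layer fields and activations; X is n x input
.forward_pass <- function(model, X) {
  spec <- model$spec
  nl <- length(model$weights)
  fields <- vector("list", nl)
  acts <- vector("list", nl + 1L)
  acts[[1L]] <- X
  for (l in seq_len(nl)) {
    v <- acts[[l]] %*% t(model$weights[[l]])
    v <- sweep(v, 2L, model$biases[[l]], `+`)
    fields[[l]] <- v
    if (l < nl) {
      acts[[l + 1L]] <- .activate(v, spec$activation, spec$sigmoid_slope)
    } else {
      acts[[l + 1L]] <- if (spec$output_mode == "regression")
        .sigmoid(v, spec$sigmoid_slope) else .softmax_rows(v)
    }
  }
  list(fields = fields, acts = acts)
}

#' Forward pass of the network
#'
#' @param model an `mlp_model`.
#' @param x feature vector, or n x input matrix of feature vectors.
#' @return matrix (n x output) of network outputs: in regression mode each
#'   entry is a sigmoid in (0, 1); in classification mode rows are softmax
#'   probabilities summing to 1.
#' @export
mlp_forward <- function(model, x) {
  stopifnot(inherits(model, "mlp_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != model$spec$input)
    stop(sprintf("input width %d does not match network input %d",
                 ncol(x), model$spec$input))
  if (!all(is.finite(x))) stop("non-finite network input")
  .forward_pass(model, x)$acts[[length(model$weights) + 1L]]
}

#' Mean error energy of the network on a data set
#'
#' Loss used throughout training: the instantaneous error energy
#' xi = 1/2 (d - y)^2 summed over output neurons, averaged over samples.
#'
#' @param model an `mlp_model`.
#' @param X n x input feature matrix.
#' @param D n x output target matrix in `[0, 1]`.
#' @return scalar mean error energy.
#' @export
net_loss <- function(model, X, D) {
  Y <- mlp_forward(model, X)
  mean(rowSums(0.5 * (D - Y)^2))
}

#' Backpropagated gradients of the mean error energy
#'
#' Analytic gradients of [net_loss()] with respect to every weight and
#' bias: output deltas eps * phi'(v), hidden deltas by the chain rule.
#' Returned on the gradient-descent convention (positive gradient of the
#' loss), so the delta-rule update is `-lr * gW`.
#'
#' @inheritParams net_loss
#' @return list with `gW` (list of matrices), `gb` (list of vectors) and
#'   `loss`.
#' @export
net_gradients <- function(model, X, D) {
  spec <- model$spec
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  D <- as.matrix(D)
  n <- nrow(X)
  fp <- .forward_pass(model, X)
  nl <- length(model$weights)
  Y <- fp$acts[[nl + 1L]]
  eps <- D - Y
  # output delta: d loss / d v  (negative of the classical delta)
  if (spec$output_mode == "regression") {
    dL_dv <- -eps * .activate_deriv(Y, fp$fields[[nl]], "sigmoid",
                                    spec$sigmoid_slope)
  } else {
    # softmax with squared-error loss: J^T eps per row
    dL_dv <- Y * (rowSums(eps * Y) - eps)
  }
  gW <- vector("list", nl); gb <- vector("list", nl)
  delta <- dL_dv
  for (l in rev(seq_len(nl))) {
    gW[[l]] <- crossprod(delta, fp$acts[[l]]) / n
    gb[[l]] <- colMeans(delta)
    if (l > 1L) {
      back <- delta %*% model$weights[[l]]
      delta <- back * .activate_deriv(fp$acts[[l]], fp$fields[[l - 1L]],
                                      spec$activation, spec$sigmoid_slope)
    }
  }
  list(gW = gW, gb = gb, loss = mean(rowSums(0.5 * eps^2)))
}

#' Train the network
#'
#' Full-batch training for `spec$epochs` epochs. `"sgd"` applies the delta
#' rule with momentum: dw(n) = alpha dw(n-1) + eta * (-gradient), where the
#' gradient term is delta times the presynaptic activation. `"adam"`
#' applies Adam (beta1 0.9, beta2 0.999, eps 1e-8) to the same gradients.
#' The per-epoch mean error energy is recorded in `model$trace`.
#'
#' @param model an `mlp_model` from [init_network()].
#' @param x n x input feature matrix, or a `feature_matrix`.
#' @param targets n x 5 matrix of intensities in `[0, 1]` (taken from the
#'   `feature_matrix` if omitted).
#' @return the trained `mlp_model`.
#' @export
train_network <- function(model, x, targets = NULL) {
  stopifnot(inherits(model, "mlp_model"))
  if (inherits(x, "feature_matrix")) {
    targets <- x$targets
    feature_names <- colnames(x$x)
    x <- x$x
  } else feature_names <- colnames(x)
  if (is.null(targets)) stop("`targets` required")
  X <- as.matrix(x); D <- as.matrix(targets)
  if (nrow(X) == 0L) stop("empty training set")
  if (any(D < 0 | D > 1)) stop("targets must lie in [0, 1]")
  spec <- model$spec
  vel_W <- lapply(model$weights, function(w) w * 0)
  vel_b <- lapply(model$biases, function(b) b * 0)
  mW <- vel_W; vW <- vel_W; mb <- vel_b; vb <- vel_b
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  trace <- numeric(spec$epochs)
  for (epoch in seq_len(spec$epochs)) {
    g <- net_gradients(model, X, D)
    if (!is.finite(g$loss))
      stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
    trace[epoch] <- g$loss
    if (spec$optimizer == "sgd") {
      for (l in seq_along(model$weights)) {
        vel_W[[l]] <- spec$momentum * vel_W[[l]] - spec$lr * g$gW[[l]]
        vel_b[[l]] <- spec$momentum * vel_b[[l]] - spec$lr * g$gb[[l]]
        model$weights[[l]] <- model$weights[[l]] + vel_W[[l]]
        model$biases[[l]] <- model$biases[[l]] + vel_b[[l]]
      }
    } else {
      for (l in seq_along(model$weights)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * g$gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * g$gW[[l]]^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * g$gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * g$gb[[l]]^2
        mW_hat <- mW[[l]] / (1 - beta1^epoch)
        vW_hat <- vW[[l]] / (1 - beta2^epoch)
        mb_hat <- mb[[l]] / (1 - beta1^epoch)
        vb_hat <- vb[[l]] / (1 - beta2^epoch)
        model$weights[[l]] <- model$weights[[l]] -
          spec$lr * mW_hat / (sqrt(vW_hat) + adam_eps)
        model$biases[[l]] <- model$biases[[l]] -
          spec$lr * mb_hat / (sqrt(vb_hat) + adam_eps)
      }
    }
  }
  model$trace <- trace
  model$feature_names <- feature_names
  model
}

#' Predict emotion intensities
#'
#' Row-wise forward pass. When the model was trained from a
#' `feature_matrix`, prediction checks that the column names match the
#' training manifest.
#'
#' @param model a trained `mlp_model`.
#' @param x feature matrix (numeric or `feature_matrix`).
#' @return n x 5 intensity matrix with columns [EMOTIONS].
#' @export
predict_emotions <- function(model, x) {
  if (inherits(x, "feature_matrix")) x <- x$x
  x <- as.matrix(x)
  if (!is.null(model$feature_names) && !is.null(colnames(x)) &&
      !identical(colnames(x), model$feature_names))
    stop("feature columns do not match the training manifest")
  out <- mlp_forward(model, x)
  colnames(out) <- EMOTIONS[seq_len(min(5L, ncol(out)))]
  out
}
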