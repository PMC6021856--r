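sigmoid <- function(x) 1 / (1 + exp(-x))

#' Rectified linear unit
#' @param x Numeric array.
#' @return `max(0, x)` elementwise.
#' @export
relu <- function(x) pmax(x, 0)

#' Binary log loss
#'
#' Mean binary cross-entropy between targets `y` in \{0,1\} and predicted
#' probabilities `yhat`:
#' `-(1/N) * sum(y*log(yhat) + (1-y)*log(1-yhat))`.
#' A predictor stuck at 0.5 scores exactly `log(2)`; a perfect predictor
#' approaches 0.
#'
#' @param y Targets in `[0, 1]`.
#' @param yhat Predictions in `(0, 1)`; clipped to `[1e-12, 1 - 1e-12]`.
#' @return Scalar mean loss.
#' @export
log_loss <- function(y, yhat) {
  yhat <- pmin(pmax(yhat, 1e-12), 1 - 1e-12)
  -mean(y * log(yhat) + (1 - y) * log(1 - yhat))
}

#' GRU cell parameters
#'
#' @param input_size,hidden_size Dimensions.
#' @param W_z,W_r,W_h Input-to-gate matrices (`hidden_size` x `input_size`).
#' @param U_z,U_r,U_h Recurrent matrices (`hidden_size` x `hidden_size`).
#' @param b_z,b_r,b_h Bias vectors (length `hidden_size`).
#' @return A `gru_cell_params` list.
#' @export
gru_cell_params <- function(input_size, hidden_size,
                            W_z, W_r, W_h, U_z, U_r, U_h, b_z, b_r, b_h) {
  p <- list(W_z = W_z, W_r = W_r, W_h = W_h,
            U_z = U_z, U_r = U_r, U_h = U_h,
            b_z = b_z, b_r = b_r, b_h = b_h,
            input_size = input_size, hidden_size = hidden_size)
  for (nm in c("W_z", "W_r", "W_h")) {
    if (!all(dim(p[[nm]]) == c(hidden_size, input_size))) {
      stop(nm, " must be hidden_size x input_size")
    }
  }
  for (nm in c("U_z", "U_r", "U_h")) {
    if (!all(dim(p[[nm]]) == c(hidden_size, hidden_size))) {
      stop(nm, " must be square of size hidden_size")
    }
  }
  for (nm in c("b_z", "b_r", "b_h")) {
    if (length(p[[nm]]) != hidden_size) stop(nm, " must have length hidden_size")
  }
  structure(p, class = "gru_cell_params")
}

#' One forward step of a gated recurrent unit
#'
#' Computes the update gate `z = sigmoid(W_z x + U_z h_prev + b_z)`, the
#' reset gate `r = sigmoid(W_r x + U_r h_prev + b_r)`, the candidate state
#' `tanh(W_h x + U_h (r o h_prev) + b_h)` and the new state
#' `h = (1 - z) o h_prev + z o candidate`, where `o` is the Hadamard
#' product.
#'
#' @param params A [gru_cell_params()].
#' @param x_t Input vector (length `input_size`).
#' @param h_prev Previous state vector (length `hidden_size`).
#' @return The new state vector `h_t`.
#' @export
gru_cell_forward <- function(params, x_t, h_prev) {
  if (length(x_t) != params$input_size) stop("x_t has wrong length")
  if (length(h_prev) != params$hidden_size) stop("h_prev has wrong length")
  z <- sigmoid(as.numeric(params$W_z %*% x_t + params$U_z %*% h_prev) + params$b_z)
  r <- sigmoid(as.numeric(params$W_r %*% x_t + params$U_r %*% h_prev) + params$b_r)
  cand <- tanh(as.numeric(params$W_h %*% x_t + params$U_h %*% (r * h_prev)) + params$b_h)
  (1 - z) * h_prev + z * cand
}

# sliding-window design matrix for 1-D cross-correlation along time:
# column (i-1)*k + u holds x[t + u - 1, i] for output time t
time_embed <- function(x, k) {
  T_in <- nrow(x); n_in <- ncol(x)
  T_out <- T_in - k + 1L
  out <- matrix(0, T_out, k * n_in)
  for (i in seq_len(n_in)) {
    for (u in seq_len(k)) {
      out[, (i - 1L) * k + u] <- x[u:(u + T_out - 1L), i]
    }
  }
  out
}

# adjoint of time_embed: scatter-add gradient rows back onto the input
time_unembed <- function(dE, T_in, n_in, k) {
  T_out <- T_in - k + 1L
  dX <- matrix(0, T_in, n_in)
  for (i in seq_len(n_in)) {
    for (u in seq_len(k)) {
      idx <- u:(u + T_out - 1L)
      dX[idx, i] <- dX[idx, i] + dE[, (i - 1L) * k + u]
    }
  }
  dX
}

#' 1-D convolutional layer parameters
#'
#' Kernels slide along the time axis only. `kernels` is a 3-D array of
#' dimension `(kernel_size, n_in, n_out)`; `biases` has length `n_out`.
#'
#' @param kernels Kernel array `(kernel_size, n_in, n_out)`.
#' @param biases Bias vector (length `n_out`).
#' @param pool Max-pool width (a `k x 1` patch along time); 1 disables
#'   pooling.
#' @return A `conv1d_layer_params` list.
#' @export
conv1d_layer_params <- function(kernels, biases, pool = 2) {
  stopifnot(length(dim(kernels)) == 3, length(biases) == dim(kernels)[3],
            pool >= 1)
  structure(list(kernels = kernels, biases = biases, pool = as.integer(pool),
                 kernel_size = dim(kernels)[1], n_in = dim(kernels)[2],
                 n_out = dim(kernels)[3]),
            class = "conv1d_layer_params")
}

# (kernel_size * n_in) x n_out matrix matching the time_embed layout
conv_kernel_matrix <- function(params) {
  matrix(params$kernels, nrow = params$kernel_size * params$n_in,
         ncol = params$n_out)
}

#' Forward pass of a 1-D convolutional layer
#'
#' Computes `y_j = ReLU(b_j + sum_i k_ij * x_i)` with the kernels sliding
#' along time (valid cross-correlation, the usual CNN convention),
#' followed by max-pooling over non-overlapping `pool x 1` time patches.
#'
#' @param params A [conv1d_layer_params()].
#' @param x Input, time x maps matrix.
#' @return Output time x `n_out` matrix (pooled).
#' @export
conv1d_forward <- function(params, x) {
  x <- as.matrix(x)
  if (ncol(x) != params$n_in) stop("input has wrong number of maps")
  if (nrow(x) < params$kernel_size) stop("input shorter than the receptive field")
  E <- time_embed(x, params$kernel_size)
  A <- sweep(E %*% conv_kernel_matrix(params), 2, params$biases, "+")
  R <- relu(A)
  p <- params$pool
  if (p <= 1) return(R)
  n_groups <- nrow(R) %/% p
  if (n_groups == 0) stop("pooling width exceeds the convolved length")
  out <- matrix(0, n_groups, ncol(R))
  for (g in seq_len(n_groups)) {
    rows <- ((g - 1L) * p + 1L):(g * p)
    out[g, ] <- apply(R[rows, , drop = FALSE], 2, max)
  }
  out
}
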