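#' Three-layer perceptron parameters
#'
#' The surrogate is a single-hidden-layer perceptron with hyperbolic-tangent
#' hidden units and a linear output, operating on standardized inputs and
#' producing a standardized output:
#' \deqn{\hat y = b_o + \sum_k w^{ho}_k \tanh\!\big(b^h_k + \sum_i w^{ih}_{ki} x_i\big)}
#'
#' @param w_ih hidden-by-input weight matrix (`n_hidden` x `n_in`).
#' @param b_h hidden bias vector (length `n_hidden`).
#' @param w_ho output weight vector (length `n_hidden`).
#' @param b_o output bias (scalar).
#' @param input_names optional labels for the inputs (default
#'   `c("etoh", "sl", "time")` when `n_in == 3`).
#' @return object of class `mlp_params`.
#' @export
mlp_params <- function(w_ih, b_h, w_ho, b_o, input_names = NULL) {
  w_ih <- as.matrix(w_ih)
  b_h <- as.numeric(b_h)
  w_ho <- as.numeric(w_ho)
  stop_if_not_scalar_number(b_o, "b_o")
  h <- nrow(w_ih)
  if (length(b_h) != h || length(w_ho) != h) {
    stop("inconsistent shapes: w_ih has ", h, " hidden rows but b_h/w_ho have ",
         length(b_h), "/", length(w_ho), " entries", call. = FALSE)
  }
  if (!all(is.finite(w_ih)) || !all(is.finite(b_h)) || !all(is.finite(w_ho))) {
    stop("non-finite weight encountered", call. = FALSE)
  }
  if (is.null(input_names)) {
    input_names <- if (ncol(w_ih) == 3L) c("etoh", "sl", "time") else
      paste0("x", seq_len(ncol(w_ih)))
  }
  if (length(input_names) != ncol(w_ih)) {
    stop("'input_names' length must equal the input count", call. = FALSE)
  }
  structure(list(w_ih = w_ih, b_h = b_h, w_ho = w_ho, b_o = as.numeric(b_o),
                 n_in = ncol(w_ih), n_hidden = h, input_names = input_names),
            class = "mlp_params")
}

#' Forward pass of the perceptron
#'
#' @param params an [mlp_params()].
#' @param x_std standardized inputs: a vector of length `n_in` or a matrix
#'   with `n_in` columns.
#' @return standardized predictions, one per input row.
#' @export
mlp_forward <- function(params, x_std) {
  stopifnot(inherits(params, "mlp_params"))
  if (is.null(dim(x_std))) x_std <- matrix(x_std, nrow = 1)
  x_std <- as.matrix(x_std)
  if (ncol(x_std) != params$n_in) {
    stop(sprintf("input has %d columns, network expects %d",
                 ncol(x_std), params$n_in), call. = FALSE)
  }
  a <- tanh(sweep(x_std %*% t(params$w_ih), 2, params$b_h, "+"))
  drop(a %*% params$w_ho) + params$b_o
}

# Pack/unpack the free parameters as one vector, order:
# vec(w_ih) column-major, b_h, w_ho, b_o  (5h + 1 entries for 3 inputs)
mlp_pack <- function(params) {
  c(as.vector(params$w_ih), params$b_h, params$w_ho, params$b_o)
}

mlp_unpack <- function(theta, n_hidden, n_in, input_names = NULL) {
  h <- n_hidden
  w_ih <- matrix(theta[seq_len(h * n_in)], nrow = h, ncol = n_in)
  b_h <- theta[h * n_in + seq_len(h)]
  w_ho <- theta[h * n_in + h + seq_len(h)]
  b_o <- theta[h * n_in + 2 * h + 1]
  mlp_params(w_ih, b_h, w_ho, b_o, input_names = input_names)
}

# Residuals r = yhat - y and Jacobian d(yhat)/d(theta) for LM training.
# Columns of J follow mlp_pack order. Entirely matrix-vectorized.
mlp_residual_jacobian <- function(theta, X, y, n_hidden, with_jacobian = TRUE) {
  h <- n_hidden
  n_in <- ncol(X)
  w_ih <- matrix(theta[seq_len(h * n_in)], nrow = h, ncol = n_in)
  b_h <- theta[h * n_in + seq_len(h)]
  w_ho <- theta[h * n_in + h + seq_len(h)]
  b_o <- theta[h * n_in + 2 * h + 1]
  tpre <- sweep(X %*% t(w_ih), 2, b_h, "+")
  tact <- tanh(tpre)                      # n x h
  yhat <- drop(tact %*% w_ho) + b_o
  r <- yhat - y
  if (!with_jacobian) return(list(r = r, yhat = yhat))
  d <- (1 - tact^2) * rep(w_ho, each = nrow(X))   # n x h: d yhat / d b_h
  jw <- do.call(cbind, lapply(seq_len(n_in), function(i) d * X[, i]))
  J <- cbind(jw, d, tact, 1)
  list(r = r, yhat = yhat, J = J)
}
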