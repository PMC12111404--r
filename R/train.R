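#' Train the perceptron surrogate by Levenberg-Marquardt
#'
#' Standardizes inputs and output, initializes all weights and biases
#' uniformly in (-0.5, 0.5) from `seed`, and minimizes the penalized sum of
#' squared standardized residuals
#' \deqn{Q(\theta) = \sum_j r_j(\theta)^2 + \alpha \|\theta\|^2}
#' by damped Gauss-Newton (Levenberg-Marquardt with Marquardt diagonal
#' scaling). A step is accepted only if it reduces `Q`; the damping factor
#' is divided by 10 on acceptance and multiplied by 10 on rejection.
#' Training stops at `max_iter` iterations, when the accepted step falls
#' below `step_tol` (relative), or when the gradient infinity-norm falls
#' below `grad_tol`.
#'
#' The small default weight penalty (`weight_decay = 0.01`) matters: a
#' 10-hidden network has 51 free parameters against a 33-run table, so the
#' unpenalized least-squares problem is underdetermined and LM converges to
#' exact interpolants whose behavior between and beyond the design points
#' is arbitrary — useless for optimization and for connection-weight
#' importance. The penalty keeps the fit in the smooth regime while leaving
#' training R-squared above 0.999 on noiseless tables. Set it to 0 for pure
#' least squares.
#'
#' @param table an [experiment_table()].
#' @param n_hidden number of hidden neurons (>= 1); 10 is the reference
#'   topology.
#' @param seed integer seed for weight initialization.
#' @param max_iter,lambda0,step_tol,grad_tol Levenberg-Marquardt controls:
#'   iteration cap (200), initial damping (1e-3), relative step tolerance
#'   (1e-10), gradient infinity-norm tolerance (1e-8).
#' @param weight_decay ridge penalty \eqn{\alpha} on the packed parameter
#'   vector, standardized scale (default 0.01; 0 disables).
#' @return object of class `mlp_fit`: `params` ([mlp_params()]), `x_scaler`
#'   and `y_scaler` ([fit_scaler()]), `r2` and `mae` on the original
#'   (destandardized) scale over the training rows, `sse` (standardized,
#'   unpenalized), `objective` (penalized), `objective_trace` (accepted
#'   values, non-increasing), `seed`, `n_iter`, `converged`.
#' @seealso [evaluate_fit()], [fit_best()], [select_topology()].
#' @export
train_lm <- function(table, n_hidden = 10, seed = 1, max_iter = 200,
                     lambda0 = 1e-3, step_tol = 1e-10, grad_tol = 1e-8,
                     weight_decay = 0.01) {
  stopifnot(inherits(table, "experiment_table"))
  stop_if_not_scalar_number(n_hidden, "n_hidden")
  stop_if_not_scalar_number(weight_decay, "weight_decay", allow_negative = FALSE)
  n_hidden <- as.integer(n_hidden)
  if (n_hidden < 1L) stop("'n_hidden' must be at least 1", call. = FALSE)

  xraw <- as.matrix(table[, c("etoh_pct", "sl_ml_per_g", "time_min")])
  yraw <- table$tpc_mg_gae_per_100g
  x_scaler <- fit_scaler(xraw)
  y_scaler <- fit_scaler(matrix(yraw, ncol = 1,
                                dimnames = list(NULL, "tpc_mg_gae_per_100g")))
  X <- scaler_apply(x_scaler, xraw)
  y <- drop(scaler_apply(y_scaler, matrix(yraw, ncol = 1)))

  n_par <- 5L * n_hidden + 1L
  set.seed(seed)
  theta <- runif(n_par, -0.5, 0.5)
  a <- weight_decay

  rj <- mlp_residual_jacobian(theta, X, y, n_hidden)
  obj <- sum(rj$r^2) + a * sum(theta^2)
  obj_trace <- obj
  lambda <- lambda0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- drop(crossprod(rj$J, rj$r)) + a * theta
    if (max(abs(g)) < grad_tol) { converged <- TRUE; break }
    H <- crossprod(rj$J)
    diag(H) <- diag(H) + a
    dH <- pmax(diag(H), 1e-12)
    accepted <- FALSE
    for (try in seq_len(40)) {
      step <- tryCatch(
        solve(H + lambda * diag(dH, n_par), -g),
        error = function(e) NULL
      )
      if (!is.null(step)) {
        cand <- theta + step
        rj_new <- mlp_residual_jacobian(cand, X, y, n_hidden)
        obj_new <- sum(rj_new$r^2) + a * sum(cand^2)
        if (is.finite(obj_new) && obj_new < obj) {
          theta <- cand
          rj <- rj_new
          obj <- obj_new
          obj_trace <- c(obj_trace, obj)
          lambda <- lambda / 10
          accepted <- TRUE
          if (sqrt(sum(step^2)) < step_tol * (1 + sqrt(sum(theta^2)))) {
            converged <- TRUE
          }
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!accepted || converged) {
      # a stall with tiny gradient still counts as converged
      if (!accepted) converged <- max(abs(g)) < sqrt(grad_tol)
      break
    }
  }

  params <- mlp_unpack(theta, n_hidden, ncol(X))
  params$input_names <- c("etoh", "sl", "time")
  fit <- structure(
    list(params = params, x_scaler = x_scaler, y_scaler = y_scaler,
         r2 = NA_real_, mae = NA_real_, sse = sum(rj$r^2), objective = obj,
         objective_trace = obj_trace, weight_decay = a,
         seed = as.integer(seed), n_iter = iter, converged = converged),
    class = "mlp_fit"
  )
  m <- evaluate_fit(fit, table)
  fit$r2 <- m$r2
  fit$mae <- m$mae
  fit
}

#' Predict TPC yield from a fitted surrogate
#'
#' @param object an `mlp_fit` from [train_lm()].
#' @param newdata data.frame with columns `etoh_pct`, `sl_ml_per_g`,
#'   `time_min`, or a numeric matrix with three columns in that order.
#' @param ... unused.
#' @return predicted yields on the original scale, mg GAE/100 g.
#' @export
predict.mlp_fit <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, c("etoh_pct", "sl_ml_per_g", "time_min")])
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  y_std <- mlp_forward(object$params, scaler_apply(object$x_scaler, newdata))
  drop(scaler_invert(object$y_scaler, matrix(y_std, ncol = 1)))
}

#' Goodness of fit on the original scale
#'
#' Computes the coefficient of determination `r2 = 1 - SS_res/SS_tot` and
#' the mean absolute error, both after mapping predictions back to
#' mg GAE/100 g.
#'
#' @param fit an `mlp_fit`.
#' @param table an [experiment_table()] to evaluate on (training table or
#'   held-out rows).
#' @return list with `r2` and `mae`.
#' @export
evaluate_fit <- function(fit, table) {
  stopifnot(inherits(fit, "mlp_fit"), inherits(table, "experiment_table"))
  y <- table$tpc_mg_gae_per_100g
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("constant outcome: R-squared undefined", call. = FALSE)
  yhat <- predict(fit, table)
  list(r2 = 1 - sum((y - yhat)^2) / ss_tot, mae = mean(abs(y - yhat)))
}

#' K-fold cross-validated fit metrics
#'
#' Optional held-out evaluator: splits the table into `k` seeded folds,
#' refits on each training part and pools out-of-fold predictions into one
#' R-squared/MAE pair. Not used by topology selection, which follows the
#' repeated-training protocol on the full table.
#'
#' @param table an [experiment_table()].
#' @param n_hidden hidden-layer size.
#' @param k number of folds (default 5).
#' @param seed integer seed for the fold assignment and the fits.
#' @param ... passed to [train_lm()].
#' @return list with `r2`, `mae` (pooled out-of-fold, original scale).
#' @export
crossval_fit <- function(table, n_hidden = 10, k = 5, seed = 1, ...) {
  stopifnot(inherits(table, "experiment_table"))
  n <- nrow(table)
  if (k < 2 || k > n - 4) stop("'k' must be in [2, nrow - 4]", call. = FALSE)
  set.seed(derive_seed(seed, 303))
  fold <- sample(rep_len(seq_len(k), n))
  yhat <- numeric(n)
  for (f in seq_len(k)) {
    tr <- table[fold != f, , drop = FALSE]
    tr <- experiment_table(tr$etoh_pct, tr$sl_ml_per_g, tr$time_min,
                           tr$tpc_mg_gae_per_100g)
    fit <- train_lm(tr, n_hidden = n_hidden, seed = derive_seed(seed, 303, f),
                    ...)
    yhat[fold == f] <- predict(fit, table[fold == f, , drop = FALSE])
  }
  y <- table$tpc_mg_gae_per_100g
  list(r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
       mae = mean(abs(y - yhat)))
}

#' Best-of-inits fit
#'
#' Runs `n_inits` trainings from different seeded initializations and keeps
#' the one with the lowest penalized objective (for `weight_decay = 0`
#' that is the lowest standardized sum of squares). Mirrors the repeated-
#' initialization protocol used for topology selection.
#'
#' @param table an [experiment_table()].
#' @param n_hidden hidden-layer size.
#' @param n_inits number of random initializations (default 10).
#' @param seed master seed; init seeds are derived via [derive_seed()].
#' @param ... passed to [train_lm()].
#' @return the best `mlp_fit`; its `seed` field records the winning derived
#'   seed.
#' @export
fit_best <- function(table, n_hidden = 10, n_inits = 10, seed = 1, ...) {
  stop_if_not_scalar_number(n_inits, "n_inits")
  best <- NULL
  for (i in seq_len(n_inits)) {
    f <- train_lm(table, n_hidden = n_hidden,
                  seed = derive_seed(seed, 101, n_hidden, i), ...)
    if (is.null(best) || f$objective < best$objective) best <- f
  }
  best
}
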