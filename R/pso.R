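#' Particle swarm configuration
#'
#' Defaults follow the setup used for dephenolization optimization: 20
#' particles, 800 iterations, personal coefficient c1 = 1.5, global
#' coefficient c2 = 2, and a constant inertia weight of 0.729 (the Clerc
#' constriction value, stable with these coefficients). Initial positions
#' are uniform within the process box (a nominal initial span wider than
#' the box is truncated to it) and initial velocities uniform within plus
#' or minus half the axis range.
#'
#' @param swarm_size particles (>= 2, default 20).
#' @param max_iter iterations (default 800).
#' @param c1,c2 personal and global learning coefficients (default 1.5, 2).
#' @param inertia constant inertia weight in (0, 1.2), default 0.729.
#' @param seed integer seed.
#' @return object of class `pso_config`.
#' @export
pso_config <- function(swarm_size = 20, max_iter = 800, c1 = 1.5, c2 = 2.0,
                       inertia = 0.729, seed = 1) {
  stop_if_not_scalar_number(swarm_size, "swarm_size")
  stop_if_not_scalar_number(max_iter, "max_iter")
  if (swarm_size < 2) stop("'swarm_size' must be at least 2", call. = FALSE)
  if (c1 <= 0 || c2 <= 0) stop("'c1' and 'c2' must be positive", call. = FALSE)
  if (inertia <= 0 || inertia >= 1.2) {
    stop("'inertia' must lie in (0, 1.2)", call. = FALSE)
  }
  structure(list(swarm_size = as.integer(swarm_size),
                 max_iter = as.integer(max_iter),
                 c1 = c1, c2 = c2, inertia = inertia,
                 seed = as.integer(seed)),
            class = "pso_config")
}

#' Minimize an objective over the process box by particle swarm
#'
#' Velocity update per particle and dimension:
#' `v <- inertia*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` with
#' `r1, r2 ~ U(0,1)` drawn independently per dimension. Velocities are
#' capped at the per-axis range; positions leaving the box are clamped to
#' the violated bound and the offending velocity component is zeroed
#' (absorbing walls). Fully deterministic for a given config seed.
#'
#' @param objective function of a numeric vector `c(etoh, sl, time)`
#'   returning a finite scalar, or — with `vectorized = TRUE` — of an
#'   n-by-3 matrix returning n values.
#' @param bounds a [process_bounds()].
#' @param config a [pso_config()].
#' @param vectorized whether `objective` accepts a matrix of positions.
#' @return object of class `pso_result`: `best_x` (named numeric), `best_f`,
#'   `history` (best-so-far objective per iteration, non-increasing),
#'   `n_evals`, and `restart_spread` (0 for a single run; filled in by
#'   [optimize_surrogate()]).
#' @export
pso_minimize <- function(objective, bounds = process_bounds(),
                         config = pso_config(), vectorized = FALSE) {
  stopifnot(inherits(config, "pso_config"))
  bm <- bounds_matrix(bounds)
  lo <- bm[, 1]; hi <- bm[, 2]; rng <- hi - lo
  d <- 3L
  np <- config$swarm_size
  f_mat <- if (vectorized) {
    function(X) objective(X)
  } else {
    function(X) apply(X, 1, objective)
  }

  set.seed(config$seed)
  X <- sweep(sweep(matrix(runif(np * d), np, d), 2, rng, "*"), 2, lo, "+")
  V <- sweep(matrix(runif(np * d, -0.5, 0.5), np, d), 2, rng, "*")

  fx <- f_mat(X)
  n_evals <- np
  if (any(is.na(fx)) || any(!is.finite(fx))) {
    stop("objective returned NaN/Inf at an initial position; first bad point: ",
         paste(signif(X[which(!is.finite(fx))[1], ], 6), collapse = ", "),
         call. = FALSE)
  }
  P <- X
  fp <- fx
  g_idx <- which.min(fp)
  gbest <- P[g_idx, ]
  fg <- fp[g_idx]
  history <- numeric(config$max_iter)

  for (it in seq_len(config$max_iter)) {
    r1 <- matrix(runif(np * d), np, d)
    r2 <- matrix(runif(np * d), np, d)
    V <- config$inertia * V +
      config$c1 * r1 * (P - X) +
      config$c2 * r2 * sweep(-X, 2, gbest, "+")
    V <- pmin(pmax(V, matrix(-rng, np, d, byrow = TRUE)),
              matrix(rng, np, d, byrow = TRUE))
    X <- X + V
    for (j in seq_len(d)) {
      below <- X[, j] < lo[j]; above <- X[, j] > hi[j]
      X[below, j] <- lo[j]; X[above, j] <- hi[j]
      V[below | above, j] <- 0
    }
    fx <- f_mat(X)
    n_evals <- n_evals + np
    if (any(is.na(fx)) || any(!is.finite(fx))) {
      stop(sprintf("objective returned NaN/Inf at iteration %d", it),
           call. = FALSE)
    }
    improved <- fx < fp
    P[improved, ] <- X[improved, ]
    fp[improved] <- fx[improved]
    g_idx <- which.min(fp)
    if (fp[g_idx] < fg) {
      fg <- fp[g_idx]
      gbest <- P[g_idx, ]
    }
    history[it] <- fg
  }

  structure(list(best_x = stats::setNames(gbest, c("etoh", "sl", "time")),
                 best_f = fg, history = history, n_evals = n_evals,
                 restart_spread = 0, seed = config$seed),
            class = "pso_result")
}

#' Maximize a fitted surrogate over the process box with restarts
#'
#' Runs the particle swarm on the negated surrogate prediction from
#' `n_restarts` independent seeds (derived from `config$seed`), returns the
#' overall best, and reports the restart spread
#' `100 * (max - min) / |max|` of the per-restart best predicted yields.
#' A spread above 5% is flagged as unstable — the stability criterion used
#' to trust a swarm optimum.
#'
#' @param fit an `mlp_fit` from [train_lm()] or [fit_best()].
#' @param bounds a [process_bounds()].
#' @param config a [pso_config()].
#' @param n_restarts independent swarm runs (default 5).
#' @return a `pso_result` on the maximization scale: `best_x`, `best_f`
#'   (predicted mg GAE/100 g), `restart_bests` (per-restart best yields),
#'   `restart_spread` (%), `stable` (spread below 5%), `history` of the
#'   winning restart.
#' @export
optimize_surrogate <- function(fit, bounds = process_bounds(),
                               config = pso_config(), n_restarts = 5) {
  stopifnot(inherits(fit, "mlp_fit"))
  stop_if_not_scalar_number(n_restarts, "n_restarts")
  neg_pred <- function(X) -predict(fit, X)
  runs <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 202, r)
    runs[[r]] <- pso_minimize(neg_pred, bounds, cfg, vectorized = TRUE)
  }
  bests <- -vapply(runs, function(x) x$best_f, numeric(1)) # predicted yields
  win <- which.max(bests)
  spread <- if (n_restarts > 1) {
    100 * (max(bests) - min(bests)) / abs(max(bests))
  } else 0
  res <- runs[[win]]
  res$best_f <- bests[win]
  res$history <- -res$history
  res$restart_bests <- bests
  res$restart_spread <- spread
  res$stable <- spread < 5
  res
}

#' Exhaustive lattice search oracle
#'
#' Brute-force verification oracle for the swarm: evaluates the objective
#' on an `n_per_axis`^3 lattice over the box and returns the best node.
#' Ties are broken by the first index in row-major order over
#' (etoh, sl, time), time varying fastest.
#'
#' @param objective as in [pso_minimize()].
#' @param bounds a [process_bounds()].
#' @param n_per_axis lattice resolution (>= 11; 101 for verification runs).
#' @param maximize search for the maximum instead of the minimum.
#' @param vectorized whether `objective` accepts a matrix of positions.
#' @return list with `x` (named numeric) and `f`.
#' @export
grid_oracle <- function(objective, bounds = process_bounds(), n_per_axis = 101,
                        maximize = FALSE, vectorized = FALSE) {
  stop_if_not_scalar_number(n_per_axis, "n_per_axis")
  if (n_per_axis < 11) stop("'n_per_axis' must be at least 11", call. = FALSE)
  bm <- bounds_matrix(bounds)
  ax <- lapply(seq_len(3), function(i) {
    seq(bm[i, 1], bm[i, 2], length.out = as.integer(n_per_axis))
  })
  g <- expand.grid(time = ax[[3]], sl = ax[[2]], etoh = ax[[1]],
                   KEEP.OUT.ATTRS = FALSE)
  X <- as.matrix(g[, c("etoh", "sl", "time")])
  f <- if (vectorized) objective(X) else apply(X, 1, objective)
  idx <- if (maximize) which.max(f) else which.min(f)
  list(x = stats::setNames(X[idx, ], c("etoh", "sl", "time")), f = f[idx])
}
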