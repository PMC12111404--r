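test_that("scaler standardizes to mean 0 / sd 1 and round-trips", {
  sc <- fit_scaler(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(unname(sc$mean), 2)
  expect_equal(unname(sc$sd), 1)
  expect_equal(drop(scaler_apply(sc, matrix(c(1, 2, 3)))), c(-1, 0, 1))

  set.seed(4)
  x <- matrix(rnorm(60, mean = 50, sd = 7), ncol = 3)
  sc2 <- fit_scaler(x)
  z <- scaler_apply(sc2, x)
  expect_equal(unname(colMeans(z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(scaler_invert(sc2, z), x, tolerance = 1e-12)

  expect_error(fit_scaler(matrix(c(5, 5, 5), ncol = 1)), "constant")
})

test_that("mlp_forward matches hand evaluation", {
  h <- random_mlp(4, seed = 2)
  zero <- mlp_params(matrix(0, 4, 3), rep(0, 4), rep(0, 4), 0)
  expect_equal(mlp_forward(zero, c(1.3, -2, 0.5)), 0)

  one <- mlp_params(matrix(c(1, 0, 0), 1, 3), 0, 1, 0)
  expect_equal(mlp_forward(one, c(0.5, 9, -9)), tanh(0.5), tolerance = 1e-12)
  expect_equal(mlp_forward(one, c(0.5, 9, -9)), 0.46211716, tolerance = 1e-7)

  # zero-bias tanh network is odd in its inputs
  nb <- mlp_params(h$w_ih, rep(0, 4), h$w_ho, 0)
  x <- c(0.3, -1.1, 0.7)
  expect_equal(mlp_forward(nb, -x), -mlp_forward(nb, x), tolerance = 1e-12)

  expect_error(mlp_forward(h, c(1, 2)), "expects")
  expect_error(mlp_params(matrix(0, 3, 3), rep(0, 2), rep(0, 3), 0),
               "inconsistent")
})

test_that("analytic residual Jacobian matches central finite differences", {
  set.seed(9)
  X <- matrix(rnorm(15), 5, 3)
  y <- rnorm(5)
  for (h in c(1, 3)) {
    theta <- runif(5 * h + 1, -0.8, 0.8)
    J <- dephenolize:::mlp_residual_jacobian(theta, X, y, h)$J
    eps <- 1e-6
    Jfd <- sapply(seq_along(theta), function(j) {
      tp <- theta; tp[j] <- tp[j] + eps
      tm <- theta; tm[j] <- tm[j] - eps
      (dephenolize:::mlp_residual_jacobian(tp, X, y, h, FALSE)$r -
         dephenolize:::mlp_residual_jacobian(tm, X, y, h, FALSE)$r) / (2 * eps)
    })
    expect_equal(J, Jfd, tolerance = 1e-6)
  }
})

test_that("LM training fits a linear surface and is deterministic", {
  set.seed(1)
  e <- runif(20, 70, 90); s <- runif(20, 10, 60); tm <- runif(20, 5, 25)
  tab <- experiment_table(e, s, tm, 2 * e)
  fit <- train_lm(tab, n_hidden = 2, seed = 1)
  expect_gte(fit$r2, 0.999)

  fit2 <- train_lm(tab, n_hidden = 2, seed = 1)
  expect_identical(dephenolize:::mlp_pack(fit$params),
                   dephenolize:::mlp_pack(fit2$params))
})

test_that("accepted LM iterations never increase the objective", {
  tab <- default_noisy_table(seed = 3)
  fit <- train_lm(tab, n_hidden = 5, seed = 4)
  expect_true(all(diff(fit$objective_trace) < 0))
})

test_that("converged LM solutions are true least-squares optima (independent solver)", {
  skip_if_not_installed("minpack.lm")
  tab <- default_noiseless_table(seed = 5, n = 20)
  h <- 1L
  xs <- fit_scaler(as.matrix(tab[, 1:3]))
  ys <- fit_scaler(matrix(tab$tpc_mg_gae_per_100g, ncol = 1))
  X <- scaler_apply(xs, as.matrix(tab[, 1:3]))
  y <- drop(scaler_apply(ys, matrix(tab$tpc_mg_gae_per_100g, ncol = 1)))
  for (s in c(10, 20)) {
    fit <- train_lm(tab, n_hidden = h, seed = s, weight_decay = 0)
    expect_true(fit$converged)
    # a MINPACK polish started at our solution must find nothing to improve
    ref <- minpack.lm::nls.lm(
      par = dephenolize:::mlp_pack(fit$params),
      fn = function(p) dephenolize:::mlp_residual_jacobian(p, X, y, h, FALSE)$r,
      jac = function(p) dephenolize:::mlp_residual_jacobian(p, X, y, h)$J,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    expect_lte(fit$sse - sum(ref$fvec^2), 1e-8 * fit$sse)
  }
})

test_that("destandardized predictions are invariant to affine input rescaling", {
  tab <- default_noiseless_table(seed = 6, n = 20)
  fit <- train_lm(tab, n_hidden = 3, seed = 2)
  # rescale raw inputs; standardization must absorb the change exactly
  tab2 <- experiment_table(10 * tab$etoh_pct - 200, tab$sl_ml_per_g / 4 + 1,
                           tab$time_min * 2, tab$tpc_mg_gae_per_100g)
  fit2 <- train_lm(tab2, n_hidden = 3, seed = 2)
  p1 <- predict(fit, tab)
  p2 <- predict(fit2, tab2)
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("evaluate_fit computes R2 and MAE on the original scale", {
  tab <- default_noiseless_table(seed = 8, n = 12)
  fit <- train_lm(tab, n_hidden = 3, seed = 1)
  m <- evaluate_fit(fit, tab)
  y <- tab$tpc_mg_gae_per_100g
  yhat <- predict(fit, tab)
  expect_equal(m$r2, 1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
  expect_equal(m$mae, mean(abs(y - yhat)))
  const <- experiment_table(tab$etoh_pct, tab$sl_ml_per_g, tab$time_min,
                            rep(1, 12))
  expect_error(train_lm(const, 2, 1), "constant")
})

test_that("topology selection plateaus early on an easy surface", {
  set.seed(2)
  e <- runif(16, 70, 90); s <- runif(16, 10, 60); tm <- runif(16, 5, 25)
  tab <- experiment_table(e, s, tm, 3 * e + 50)
  scan <- select_topology(tab, hidden_sizes = 1:3, n_repeats = 2, n_inits = 2,
                          seed = 1)
  expect_lte(scan$selected, 2)
  expect_true(scan$plateau)
  expect_true(scan$selected %in% scan$scan$n_hidden)

  single <- select_topology(tab, hidden_sizes = 10, n_repeats = 1, n_inits = 1,
                            seed = 1)
  expect_equal(single$selected, 10L)
  expect_error(select_topology(tab, hidden_sizes = c(3, 2)), "increasing")
})

test_that("cross-validated metrics are finite and below the training fit", {
  tab <- default_noisy_table(seed = 12)
  cv <- crossval_fit(tab, n_hidden = 4, k = 5, seed = 3)
  fit <- train_lm(tab, n_hidden = 4, seed = 3)
  expect_true(is.finite(cv$r2) && is.finite(cv$mae))
  expect_lte(cv$r2, 1)
  expect_gte(cv$mae, 0)
})
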