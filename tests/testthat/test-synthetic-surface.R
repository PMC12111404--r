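test_that("default spec is calibrated so the noiseless box maximum is 1887.76", {
  spec <- make_default_spec()
  expect_equal(spec$e_star, 84)
  expect_equal(spec$t_star, 15)
  # y0 solves y0 * 60/(60+25) = 1887.76
  expect_equal(spec$y0, 1887.76 * 85 / 60, tolerance = 1e-12)
  expect_equal(evaluate_surface(spec, 84, 60, 15), 1887.76, tolerance = 1e-9)
})

test_that("surface is unimodal in ethanol/time and saturating in S/L", {
  spec <- make_default_spec()
  expect_lt(evaluate_surface(spec, 70, 60, 15), evaluate_surface(spec, 84, 60, 15))
  expect_lt(evaluate_surface(spec, 84, 60, 5), evaluate_surface(spec, 84, 60, 15))
  # monotone increasing in sl
  sl <- seq(10, 60, by = 5)
  y <- evaluate_surface(spec, 84, sl, 15)
  expect_true(all(diff(y) > 0))
  # sl -> 0+ kills the yield
  expect_lt(evaluate_surface(spec, 84, 1e-9, 15), 1e-4)
  expect_error(evaluate_surface(spec, 84, 0, 15), "positive")
})

test_that("process bounds and spec invariants are enforced", {
  expect_error(process_bounds(etoh_range = c(90, 70)), "lo < hi")
  expect_error(surface_spec(y0 = -1, e_star = 84, sigma_e = 15, k_r = 25,
                            t_star = 15, sigma_t = 20), "positive")
  expect_error(surface_spec(y0 = 1, e_star = 84, sigma_e = 15, k_r = 25,
                            t_star = 15, sigma_t = 20, noise_sd = -1),
               "non-negative")
})

test_that("latin hypercube design stratifies every axis into n one-point bins", {
  n <- 33
  b <- process_bounds()
  d <- generate_design(b, n = n, scheme = "latin_hypercube", seed = 1)
  expect_equal(nrow(d), n)
  for (col in list(c("etoh_pct", 70, 90), c("sl_ml_per_g", 10, 60),
                   c("time_min", 5, 25))) {
    v <- d[[col[1]]]
    lo <- as.numeric(col[2]); hi <- as.numeric(col[3])
    expect_true(all(v >= lo & v <= hi))
    bins <- floor((v - lo) / (hi - lo) * n)
    bins[bins == n] <- n - 1
    expect_equal(sort(bins), 0:(n - 1))
  }
})

test_that("grid design with n = 8 returns the corners of the box", {
  d <- generate_design(process_bounds(), n = 8, scheme = "grid", seed = 99)
  expect_equal(nrow(d), 8)
  expect_setequal(unique(d$etoh_pct), c(70, 90))
  expect_setequal(unique(d$sl_ml_per_g), c(10, 60))
  expect_setequal(unique(d$time_min), c(5, 25))
  expect_equal(nrow(unique(d)), 8)
})

test_that("designs are deterministic per seed and reject tiny n", {
  d1 <- generate_design(n = 12, seed = 5)
  d2 <- generate_design(n = 12, seed = 5)
  d3 <- generate_design(n = 12, seed = 6)
  expect_identical(d1, d2)
  expect_false(identical(d1, d3))
  expect_error(generate_design(n = 3), "at least 4")
})

test_that("simulation equals the noiseless surface when noise_sd = 0", {
  spec <- make_default_spec(noise_sd = 0)
  d <- generate_design(n = 10, seed = 2)
  tab <- simulate_experiments(spec, d, seed = 123)
  expect_equal(tab$tpc_mg_gae_per_100g,
               evaluate_surface(spec, d$etoh_pct, d$sl_ml_per_g, d$time_min),
               tolerance = 1e-12)
})

test_that("simulated noise is centered and seed-reproducible", {
  spec <- make_default_spec()
  d <- generate_design(n = 33, seed = 1)
  mu <- evaluate_surface(spec, d$etoh_pct, d$sl_ml_per_g, d$time_min)
  tab <- simulate_experiments(spec, d, seed = 7)
  # CLT bound on the mean residual
  expect_lt(abs(mean(tab$tpc_mg_gae_per_100g - mu)),
            3 * spec$noise_sd / sqrt(33))
  expect_identical(simulate_experiments(spec, d, seed = 7)$tpc_mg_gae_per_100g,
                   tab$tpc_mg_gae_per_100g)
  expect_false(identical(
    simulate_experiments(spec, d, seed = 8)$tpc_mg_gae_per_100g,
    tab$tpc_mg_gae_per_100g))
})

test_that("true_optimum finds the constructed maximum and clamps to the box", {
  spec <- make_default_spec()
  opt <- true_optimum(spec)
  expect_equal(unname(opt$condition), c(84, 60, 15), tolerance = 1e-6)
  expect_equal(opt$yield, 1887.76, tolerance = 1e-8)
  # a time peak outside the window lands on the nearest bound
  spec2 <- surface_spec(y0 = 100, e_star = 84, sigma_e = 15, k_r = 25,
                        t_star = 40, sigma_t = 20)
  opt2 <- true_optimum(spec2)
  expect_equal(unname(opt2$condition["time"]), 25, tolerance = 1e-6)
})

test_that("main-effect shares identify the dominant input and sum below 100%", {
  spec <- make_default_spec()
  me <- true_main_effects(spec, n_mc = 20000, seed = 11)
  expect_false(me$degenerate)
  expect_identical(me$order, c("sl", "etoh", "time"))
  expect_lte(sum(me$share), 100)
  # a surface driven almost only by ethanol attributes ~everything to it
  spec_e <- surface_spec(y0 = 100, e_star = 80, sigma_e = 5, k_r = 1e-9,
                         t_star = 15, sigma_t = 1e9)
  me_e <- true_main_effects(spec_e, n_mc = 5000, seed = 2)
  expect_gt(me_e$share["etoh"], 95)
  # an essentially constant surface is flagged degenerate
  spec_c <- surface_spec(y0 = 100, e_star = 80, sigma_e = 1e9, k_r = 1e-9,
                         t_star = 15, sigma_t = 1e9)
  expect_true(true_main_effects(spec_c, n_mc = 2000, seed = 3)$degenerate)
})

test_that("default main-effect ordering is stable across Monte-Carlo seeds", {
  spec <- make_default_spec()
  hits <- sum(vapply(1:10, function(s) {
    identical(true_main_effects(spec, n_mc = 20000, seed = s)$order,
              c("sl", "etoh", "time"))
  }, logical(1)))
  expect_gte(hits, 9)
})
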