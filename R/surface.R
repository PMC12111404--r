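#' Process-variable bounds for dephenolization
#'
#' The ethanol-wash dephenolization of rapeseed cake is controlled by three
#' process variables: ethanol concentration (% v/v), solid-to-liquid ratio
#' (mL of solvent per g of cake; a "1:60 w/v" wash is 60 mL/g) and
#' ultrasound treatment time (min). `process_bounds()` builds the box over
#' which designs are generated and the optimizer searches. Defaults are the
#' operating window commonly screened for this system.
#'
#' @param etoh_range numeric pair, ethanol concentration bounds in % (default
#'   `c(70, 90)`).
#' @param sl_range numeric pair, solid-to-liquid ratio bounds in mL/g
#'   (default `c(10, 60)`).
#' @param time_range numeric pair, sonication time bounds in min (default
#'   `c(5, 25)`).
#' @return an object of class `process_bounds`: a named list of the three
#'   ranges.
#' @examples
#' b <- process_bounds()
#' b$sl_range
#' @export
process_bounds <- function(etoh_range = c(70, 90),
                           sl_range = c(10, 60),
                           time_range = c(5, 25)) {
  for (nm in c("etoh_range", "sl_range", "time_range")) {
    r <- get(nm)
    if (!is.numeric(r) || length(r) != 2L || !all(is.finite(r))) {
      stop(sprintf("'%s' must be a finite numeric pair", nm), call. = FALSE)
    }
    if (r[1] >= r[2]) {
      stop(sprintf("'%s' must satisfy lo < hi (got %g, %g)", nm, r[1], r[2]),
           call. = FALSE)
    }
  }
  structure(
    list(etoh_range = as.numeric(etoh_range),
         sl_range = as.numeric(sl_range),
         time_range = as.numeric(time_range)),
    class = "process_bounds"
  )
}

# 3x2 matrix view of the box, rows in axis order etoh, sl, time
bounds_matrix <- function(bounds) {
  stopifnot(inherits(bounds, "process_bounds"))
  rbind(etoh = bounds$etoh_range, sl = bounds$sl_range, time = bounds$time_range)
}

#' Ground-truth response surface for synthetic dephenolization experiments
#'
#' Defines a smooth, strictly positive total-phenolic-content (TPC) surface
#' over the process box, used to simulate experiment tables with a known
#' optimum and known main-effect ordering. The surface is a product of three
#' univariate factors:
#' \deqn{y(e, r, t) = y_0 \; e^{-\frac{(e - e^*)^2}{2\sigma_e^2}} \;
#'   \frac{r}{r + k_r} \; e^{-\frac{(t - t^*)^2}{2\sigma_t^2}}}
#' i.e. unimodal in ethanol concentration \eqn{e} and time \eqn{t} (peaks at
#' `e_star`, `t_star`) and monotone saturating in the solid-to-liquid ratio
#' \eqn{r} (Michaelis-Menten-type, half-saturation `k_r`). Measurement noise
#' is additive Gaussian with standard deviation `noise_sd`, truncated at
#' zero when tables are simulated.
#'
#' @param y0 surface scale, mg GAE/100 g dry cake; must be positive.
#' @param e_star,sigma_e ethanol optimum and width, %.
#' @param k_r solid-to-liquid half-saturation constant, mL/g.
#' @param t_star,sigma_t time optimum and width, min.
#' @param noise_sd measurement noise standard deviation, mg GAE/100 g
#'   (>= 0).
#' @return an object of class `surface_spec`.
#' @seealso [make_default_spec()] for the calibrated default surface,
#'   [evaluate_surface()], [simulate_experiments()].
#' @export
surface_spec <- function(y0, e_star, sigma_e, k_r, t_star, sigma_t,
                         noise_sd = 0) {
  stop_if_not_scalar_number(y0, "y0")
  stop_if_not_scalar_number(e_star, "e_star")
  stop_if_not_scalar_number(sigma_e, "sigma_e")
  stop_if_not_scalar_number(k_r, "k_r")
  stop_if_not_scalar_number(t_star, "t_star")
  stop_if_not_scalar_number(sigma_t, "sigma_t")
  stop_if_not_scalar_number(noise_sd, "noise_sd", allow_negative = FALSE)
  if (y0 <= 0) stop("'y0' must be positive", call. = FALSE)
  if (sigma_e <= 0 || sigma_t <= 0) stop("widths must be positive", call. = FALSE)
  if (k_r <= 0) stop("'k_r' must be positive", call. = FALSE)
  structure(
    list(y0 = y0, e_star = e_star, sigma_e = sigma_e, k_r = k_r,
         t_star = t_star, sigma_t = sigma_t, noise_sd = noise_sd),
    class = "surface_spec"
  )
}

#' Default calibrated synthetic surface
#'
#' Returns the surface used as the package's reference study condition. It
#' is calibrated so that the noiseless maximum over the default
#' [process_bounds()] equals 1887.76 mg GAE/100 g, attained at 84% ethanol,
#' 60 mL/g and 15 min — an interior optimum in ethanol and time with the
#' solid-to-liquid ratio at its upper bound — and so that the variance-based
#' main effects order as solid-to-liquid ratio > ethanol > time.
#'
#' With `e_star = 84`, `sigma_e = 15`, `k_r = 25`, `t_star = 15`,
#' `sigma_t = 20`, the saturation factor at the S/L upper bound is
#' 60/(60+25), so `y0 = 1887.76 * 85/60`.
#'
#' @param noise_sd measurement noise sd, mg GAE/100 g; default 40 (about 2%
#'   of the maximum yield).
#' @return a `surface_spec`.
#' @examples
#' spec <- make_default_spec()
#' evaluate_surface(spec, etoh = 84, sl = 60, time = 15) # 1887.76
#' @export
make_default_spec <- function(noise_sd = 40) {
  target_max <- 1887.76
  k_r <- 25
  sl_hi <- 60
  y0 <- target_max * (sl_hi + k_r) / sl_hi
  surface_spec(y0 = y0, e_star = 84, sigma_e = 15, k_r = k_r,
               t_star = 15, sigma_t = 20, noise_sd = noise_sd)
}

#' Evaluate the noiseless synthetic surface
#'
#' @param spec a [surface_spec()].
#' @param etoh,sl,time numeric vectors (recycled to a common length):
#'   ethanol %, solid-to-liquid ratio mL/g, time min. `sl` must be positive.
#' @return numeric vector of noiseless TPC yields, mg GAE/100 g.
#' @export
evaluate_surface <- function(spec, etoh, sl, time) {
  stopifnot(inherits(spec, "surface_spec"))
  n <- max(length(etoh), length(sl), length(time))
  etoh <- rep_len(as.numeric(etoh), n)
  sl <- rep_len(as.numeric(sl), n)
  time <- rep_len(as.numeric(time), n)
  if (any(!is.finite(etoh)) || any(!is.finite(sl)) || any(!is.finite(time))) {
    stop("process coordinates must be finite", call. = FALSE)
  }
  if (any(sl <= 0)) {
    stop("solid-to-liquid ratio 'sl' must be positive", call. = FALSE)
  }
  spec$y0 *
    exp(-(etoh - spec$e_star)^2 / (2 * spec$sigma_e^2)) *
    (sl / (sl + spec$k_r)) *
    exp(-(time - spec$t_star)^2 / (2 * spec$sigma_t^2))
}

#' Noiseless optimum of a synthetic surface over the process box
#'
#' Dense grid scan (at least 201 points per axis) followed by a local
#' Nelder-Mead polish, constrained to the box. For the default surface the
#' optimum is at (84, 60, 15) by construction; if a peak parameter lies
#' outside its range the corresponding coordinate lands on the nearest
#' bound.
#'
#' @param spec a [surface_spec()].
#' @param bounds a [process_bounds()].
#' @param n_grid grid resolution per axis (default 201, minimum 201).
#' @return list with `condition` (named numeric: etoh, sl, time) and
#'   `yield` (mg GAE/100 g).
#' @export
true_optimum <- function(spec, bounds = process_bounds(), n_grid = 201) {
  stopifnot(inherits(spec, "surface_spec"))
  n_grid <- max(201L, as.integer(n_grid))
  bm <- bounds_matrix(bounds)
  # the surface is separable: scan each axis independently, then polish
  ax <- lapply(seq_len(3), function(i) seq(bm[i, 1], bm[i, 2], length.out = n_grid))
  fe <- exp(-(ax[[1]] - spec$e_star)^2 / (2 * spec$sigma_e^2))
  fr <- ax[[2]] / (ax[[2]] + spec$k_r)
  ft <- exp(-(ax[[3]] - spec$t_star)^2 / (2 * spec$sigma_t^2))
  x0 <- c(ax[[1]][which.max(fe)], ax[[2]][which.max(fr)], ax[[3]][which.max(ft)])
  neg <- function(p) -evaluate_surface(spec, p[1], p[2], p[3])
  fit <- optim(x0, neg, method = "L-BFGS-B", lower = bm[, 1], upper = bm[, 2])
  cond <- c(etoh = fit$par[1], sl = fit$par[2], time = fit$par[3])
  list(condition = cond, yield = -fit$value)
}

#' Variance-based first-order main effects of a synthetic surface
#'
#' Monte-Carlo estimate of the Sobol first-order indices
#' \eqn{S_i = \mathrm{Var}(E[y \mid x_i]) / \mathrm{Var}(y)} under uniform
#' sampling over the process box, expressed as percentages. Used as the
#' ground-truth attribution against which connection-weight importance is
#' compared. The pick-and-freeze estimator of Sobol/Saltelli is used with
#' two independent sample matrices; shares of a non-additive surface sum to
#' less than 100%.
#'
#' @param spec a [surface_spec()].
#' @param bounds a [process_bounds()].
#' @param n_mc Monte-Carlo sample size per matrix (>= 1000).
#' @param seed integer seed.
#' @return list with `share` (named numeric, % per input: etoh, sl, time),
#'   `order` (labels sorted by decreasing share), `total_variance`, and
#'   `degenerate` (TRUE when the surface is essentially constant over the
#'   box, in which case shares are set to `NA`).
#' @export
true_main_effects <- function(spec, bounds = process_bounds(),
                              n_mc = 20000, seed = 1) {
  stopifnot(inherits(spec, "surface_spec"))
  stop_if_not_scalar_number(n_mc, "n_mc")
  if (n_mc < 1000) stop("'n_mc' must be at least 1000", call. = FALSE)
  bm <- bounds_matrix(bounds)
  set.seed(seed)
  draw <- function() {
    sapply(seq_len(3), function(i) runif(n_mc, bm[i, 1], bm[i, 2]))
  }
  A <- draw()
  B <- draw()
  f <- function(X) evaluate_surface(spec, X[, 1], X[, 2], X[, 3])
  fA <- f(A)
  fB <- f(B)
  v <- stats::var(c(fA, fB))
  labels <- c("etoh", "sl", "time")
  mu <- mean(c(fA, fB))
  if (!is.finite(v) || v <= (1e-12 * max(1, mu^2))) {
    return(list(share = stats::setNames(rep(NA_real_, 3), labels),
                order = labels, total_variance = v, degenerate = TRUE))
  }
  share <- vapply(seq_len(3), function(i) {
    ABi <- A
    ABi[, i] <- B[, i]
    # Sobol first-order, Saltelli 2010 estimator
    100 * mean(fB * (f(ABi) - fA)) / v
  }, numeric(1))
  names(share) <- labels
  list(share = share,
       order = labels[order(abs(share), decreasing = TRUE)],
       total_variance = v, degenerate = FALSE)
}
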