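#' Generate an experimental design over the process box
#'
#' Two schemes are supported. `"latin_hypercube"` stratifies each axis into
#' `n` equal-width bins with exactly one point per bin (maximin-free random
#' LHS). `"grid"` builds the smallest factorial lattice with
#' `ceiling(n^(1/3))` equally spaced levels per axis and keeps the first `n`
#' points in row-major order (axis order etoh, sl, time; time varies
#' fastest).
#'
#' @param bounds a [process_bounds()].
#' @param n number of design points (>= 4); 33 is the package's reference
#'   design size.
#' @param scheme `"latin_hypercube"` (default) or `"grid"`.
#' @param seed integer seed (only the Latin hypercube is stochastic).
#' @return data.frame with columns `etoh_pct`, `sl_ml_per_g`, `time_min`.
#' @examples
#' d <- generate_design(process_bounds(), n = 33, seed = 1)
#' nrow(d)
#' @export
generate_design <- function(bounds = process_bounds(), n = 33,
                            scheme = c("latin_hypercube", "grid"), seed = 1) {
  scheme <- match.arg(scheme)
  stop_if_not_scalar_number(n, "n")
  n <- as.integer(n)
  if (n < 4L) stop("'n' must be at least 4 design points", call. = FALSE)
  bm <- bounds_matrix(bounds)
  if (scheme == "latin_hypercube") {
    set.seed(seed)
    u <- lhs::randomLHS(n, 3L)
  } else {
    m <- as.integer(ceiling(n^(1 / 3)))
    # guard against representation error, e.g. 27^(1/3) = 3.0000000000000004
    if ((m - 1L)^3 >= n) m <- m - 1L
    lv <- lapply(seq_len(3), function(i) seq(0, 1, length.out = m))
    # row-major over (etoh, sl, time): time varies fastest
    g <- expand.grid(time = lv[[3]], sl = lv[[2]], etoh = lv[[1]],
                     KEEP.OUT.ATTRS = FALSE)
    u <- as.matrix(g[seq_len(n), c("etoh", "sl", "time")])
  }
  out <- data.frame(
    etoh_pct = bm[1, 1] + u[, 1] * diff(bm[1, ]),
    sl_ml_per_g = bm[2, 1] + u[, 2] * diff(bm[2, ]),
    time_min = bm[3, 1] + u[, 3] * diff(bm[3, ])
  )
  rownames(out) <- NULL
  out
}

#' Construct an experiment table
#'
#' An experiment table is a data.frame of design points with their measured
#' (or simulated) total phenolic yield, the training data for the surrogate.
#'
#' @param etoh_pct,sl_ml_per_g,time_min,tpc_mg_gae_per_100g numeric columns.
#' @param seed integer seed used to produce the table, or `NA`.
#' @param provenance free-text description of where the data came from.
#' @return data.frame of class `experiment_table` with attributes `seed` and
#'   `provenance`.
#' @export
experiment_table <- function(etoh_pct, sl_ml_per_g, time_min,
                             tpc_mg_gae_per_100g, seed = NA_integer_,
                             provenance = "") {
  tab <- data.frame(
    etoh_pct = as.numeric(etoh_pct),
    sl_ml_per_g = as.numeric(sl_ml_per_g),
    time_min = as.numeric(time_min),
    tpc_mg_gae_per_100g = as.numeric(tpc_mg_gae_per_100g)
  )
  if (nrow(tab) < 4L) {
    stop("an experiment table needs at least 4 rows for any model fit",
         call. = FALSE)
  }
  bad <- which(!is.finite(tab$tpc_mg_gae_per_100g) | tab$tpc_mg_gae_per_100g < 0)
  if (length(bad)) {
    stop(sprintf("negative or non-finite TPC yield in row(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(tab, seed = seed, provenance = provenance,
            class = c("experiment_table", "data.frame"))
}

#' Simulate dephenolization experiments from a ground-truth surface
#'
#' Evaluates the noiseless surface at every design point and adds Gaussian
#' measurement noise (sd `spec$noise_sd`), truncating at zero; real TPC
#' assays cannot read negative. With `noise_sd = 0` the table equals the
#' noiseless surface exactly.
#'
#' @param spec a [surface_spec()].
#' @param design data.frame from [generate_design()] (columns `etoh_pct`,
#'   `sl_ml_per_g`, `time_min`).
#' @param seed integer seed for the noise draws.
#' @return an [experiment_table()]; `provenance` records the spec
#'   parameters and seed.
#' @export
simulate_experiments <- function(spec, design, seed = 1) {
  stopifnot(inherits(spec, "surface_spec"))
  need <- c("etoh_pct", "sl_ml_per_g", "time_min")
  if (!all(need %in% names(design))) {
    stop("design must have columns etoh_pct, sl_ml_per_g, time_min",
         call. = FALSE)
  }
  mu <- evaluate_surface(spec, design$etoh_pct, design$sl_ml_per_g,
                         design$time_min)
  set.seed(seed)
  y <- pmax(0, mu + rnorm(nrow(design), 0, spec$noise_sd))
  prov <- sprintf(
    "synthetic: y0=%.6g e*=%g sig_e=%g k_r=%g t*=%g sig_t=%g noise_sd=%g seed=%d",
    spec$y0, spec$e_star, spec$sigma_e, spec$k_r, spec$t_star, spec$sigma_t,
    spec$noise_sd, as.integer(seed)
  )
  experiment_table(design$etoh_pct, design$sl_ml_per_g, design$time_min, y,
                   seed = as.integer(seed), provenance = prov)
}
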