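#' Read and write experiment tables as CSV
#'
#' The on-disk dialect is fixed: comma-separated, UTF-8, '.' decimal, exact
#' header `etoh_pct,sl_ml_per_g,time_min,tpc_mg_gae_per_100g`. Writing also
#' produces a sidecar `<path>.meta.json` holding the seed and provenance so
#' a table can be traced back to the run that made it; reading picks the
#' sidecar up when present. Round trips are lossless to full double
#' precision (values are written with 17 significant digits).
#'
#' @param path CSV path.
#' @return [read_experiments()] returns an [experiment_table()];
#'   [write_experiments()] returns `path` invisibly.
#' @export
read_experiments <- function(path) {
  header <- names(read.csv(path, nrows = 1, check.names = FALSE))
  want <- c("etoh_pct", "sl_ml_per_g", "time_min", "tpc_mg_gae_per_100g")
  missing <- setdiff(want, header)
  extra <- setdiff(header, want)
  if (length(missing) || length(extra)) {
    stop("experiment CSV header mismatch",
         if (length(missing)) paste0("; missing column(s): ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unknown column(s): ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  d <- read.csv(path, check.names = FALSE)
  for (cn in want) {
    v <- suppressWarnings(as.numeric(d[[cn]]))
    if (any(is.na(v))) {
      stop(sprintf("non-numeric or missing value in column '%s' (row %d)",
                   cn, which(is.na(v))[1]), call. = FALSE)
    }
    d[[cn]] <- v
  }
  bad <- which(d$tpc_mg_gae_per_100g < 0)
  if (length(bad)) {
    stop(sprintf("negative TPC yield in row(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  seed <- NA_integer_
  prov <- sprintf("read from %s", path)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$seed)) seed <- as.integer(meta$seed)
    if (!is.null(meta$provenance)) prov <- meta$provenance
  }
  experiment_table(d$etoh_pct, d$sl_ml_per_g, d$time_min,
                   d$tpc_mg_gae_per_100g, seed = seed, provenance = prov)
}

#' @rdname read_experiments
#' @param table an [experiment_table()].
#' @param sidecar write the `<path>.meta.json` sidecar (default TRUE).
#' @export
write_experiments <- function(table, path, sidecar = TRUE) {
  stopifnot(inherits(table, "experiment_table"))
  d <- as.data.frame(table)
  d[] <- lapply(d, function(x) format(x, digits = 17, scientific = FALSE,
                                      trim = TRUE))
  write.csv(d, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  if (sidecar) {
    jsonlite::write_json(
      list(seed = attr(table, "seed"), provenance = attr(table, "provenance")),
      paste0(path, ".meta.json"), auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

#' Serialize a fitted surrogate to JSON and back
#'
#' Stores the scaler means/sds, the weight matrices (input-hidden weights
#' row-major), and fit metadata (seed, iterations, R-squared, MAE), so a
#' trained model can be archived next to its experiment table and reloaded
#' for prediction or optimization.
#'
#' @param fit an `mlp_fit`.
#' @param path JSON path.
#' @return `write_fit()` returns `path` invisibly; `read_fit()` returns the
#'   reconstructed `mlp_fit`.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "mlp_fit"))
  p <- fit$params
  obj <- list(
    n_in = p$n_in, n_hidden = p$n_hidden, input_names = p$input_names,
    w_ih_rowmajor = as.vector(t(p$w_ih)), b_h = p$b_h, w_ho = p$w_ho,
    b_o = p$b_o,
    x_scaler = list(mean = unname(fit$x_scaler$mean),
                    sd = unname(fit$x_scaler$sd)),
    y_scaler = list(mean = unname(fit$y_scaler$mean),
                    sd = unname(fit$y_scaler$sd)),
    r2 = fit$r2, mae = fit$mae, sse = fit$sse, seed = fit$seed,
    n_iter = fit$n_iter, converged = fit$converged
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- mlp_params(
    w_ih = matrix(o$w_ih_rowmajor, nrow = o$n_hidden, ncol = o$n_in,
                  byrow = TRUE),
    b_h = o$b_h, w_ho = o$w_ho, b_o = o$b_o, input_names = o$input_names
  )
  structure(
    list(params = params,
         x_scaler = structure(list(mean = o$x_scaler$mean,
                                   sd = o$x_scaler$sd),
                              class = "standard_scaler"),
         y_scaler = structure(list(mean = o$y_scaler$mean,
                                   sd = o$y_scaler$sd),
                              class = "standard_scaler"),
         r2 = o$r2, mae = o$mae, sse = o$sse, seed = o$seed,
         n_iter = o$n_iter, converged = o$converged),
    class = "mlp_fit"
  )
}
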