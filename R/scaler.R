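#' Column standardizer (z-score)
#'
#' Both the inputs and the output are standardized before the network is
#' trained; the fitted scaler travels with the model so predictions can be
#' mapped back to original units.
#'
#' @param x numeric matrix or data.frame of columns to standardize.
#' @return object of class `standard_scaler` with per-column `mean` and
#'   sample `sd` (denominator n - 1).
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 rows to fit a scaler", call. = FALSE)
  m <- colMeans(x)
  s <- apply(x, 2, sd)
  if (any(s <= 0 | !is.finite(s))) {
    bad <- colnames(x)[s <= 0 | !is.finite(s)]
    if (is.null(bad)) bad <- which(s <= 0 | !is.finite(s))
    stop(sprintf("constant column(s) cannot be standardized: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(mean = m, sd = s), class = "standard_scaler")
}

#' @rdname fit_scaler
#' @param scaler a `standard_scaler`.
#' @export
scaler_apply <- function(scaler, x) {
  stopifnot(inherits(scaler, "standard_scaler"))
  x <- as.matrix(x)
  if (ncol(x) != length(scaler$mean)) {
    stop("column count does not match the fitted scaler", call. = FALSE)
  }
  sweep(sweep(x, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' @rdname fit_scaler
#' @export
scaler_invert <- function(scaler, x) {
  stopifnot(inherits(scaler, "standard_scaler"))
  x <- as.matrix(x)
  if (ncol(x) != length(scaler$mean)) {
    stop("column count does not match the fitted scaler", call. = FALSE)
  }
  sweep(sweep(x, 2, scaler$sd, "*"), 2, scaler$mean, "+")
}
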