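#' Connection-weight relative importance (Yoon's method)
#'
#' Attributes the trained network's output to its inputs from the weight
#' matrices alone. For input i and the single output, the signed importance
#' is
#' \deqn{RI_i = 100 \cdot \frac{\sum_k w^{ih}_{ki} w^{ho}_k}
#'   {\sum_{i'} \left| \sum_k w^{ih}_{ki'} w^{ho}_k \right|}}
#' where the sums run over hidden neurons k. Bias terms are excluded: the
#' method measures signal paths from an input through the hidden layer to
#' the output. Absolute values sum to 100%; a negative sign means that
#' increasing the input decreases the predicted yield. The importance is
#' computed on the standardized-scale network, where inputs are comparably
#' scaled by construction.
#'
#' @param params an [mlp_params()] with a single output.
#' @return object of class `relative_importance`: named numeric `ri`
#'   (signed %), `input_names`, and `rank_order` (labels sorted by
#'   decreasing absolute importance; ties broken by input declaration
#'   order).
#' @examples
#' p <- mlp_params(w_ih = matrix(c(2, 1, 1), 1), b_h = 0, w_ho = 1, b_o = 0)
#' yoon_ri(p)$ri # 50 25 25
#' @export
yoon_ri <- function(params) {
  stopifnot(inherits(params, "mlp_params"))
  num <- drop(crossprod(params$w_ih, params$w_ho)) # sum_k w_ih[k,i] * w_ho[k]
  den <- sum(abs(num))
  if (den == 0) {
    stop("all input-to-output path products cancel: relative importance undefined",
         call. = FALSE)
  }
  ri <- 100 * num / den
  names(ri) <- params$input_names
  # order() is stable, so |RI| ties fall back to declaration order
  rank_order <- params$input_names[order(-abs(ri))]
  structure(list(ri = ri, input_names = params$input_names,
                 rank_order = rank_order),
            class = "relative_importance")
}

#' @export
print.relative_importance <- function(x, ...) {
  cat("Connection-weight relative importance (signed %, |RI| sums to 100)\n")
  print(round(x$ri, 2))
  cat("rank order:", paste(x$rank_order, collapse = " > "), "\n")
  invisible(x)
}

#' Does the importance ranking match a reference ordering?
#'
#' Compares the inputs sorted by decreasing absolute importance with a
#' reference label ordering (e.g. the ground-truth main-effect order of a
#' synthetic surface). Ties in |RI| are broken by input declaration order,
#' so an exact-tie comparison is deterministic but convention-dependent.
#'
#' @param ri a `relative_importance` from [yoon_ri()].
#' @param reference_order character vector: the same labels, in the
#'   expected order of decreasing influence.
#' @return TRUE or FALSE.
#' @export
rank_agreement <- function(ri, reference_order) {
  stopifnot(inherits(ri, "relative_importance"))
  if (!setequal(ri$input_names, reference_order) ||
      length(reference_order) != length(ri$input_names)) {
    stop("reference labels do not match the network's input names",
         call. = FALSE)
  }
  identical(ri$rank_order, as.character(reference_order))
}
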