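#' Select the hidden-layer size by repeated-training mean R-squared
#'
#' For each candidate size, runs `n_repeats` repeats of `n_inits` seeded
#' trainings each, keeps every repeat's best-of-inits training R-squared,
#' and summarizes candidates by the mean and sd of those repeat bests. The
#' selected topology is the smallest size whose mean R-squared reaches 0.9
#' and whose successor improves the mean by less than `plateau` (so adding
#' neurons no longer pays); the largest scanned size qualifies on the
#' threshold alone. If no size reaches 0.9 the scan falls back to the
#' argmax and is flagged `plateau = FALSE`.
#'
#' @param table an [experiment_table()].
#' @param hidden_sizes strictly increasing candidate sizes (default 1:15).
#' @param n_repeats,n_inits repeats and initializations per repeat (default
#'   10 and 10).
#' @param seed master seed; per-(size, repeat, init) seeds are derived with
#'   [derive_seed()].
#' @param plateau minimum successor improvement that still counts as real
#'   (default 0.005).
#' @param r2_min acceptance level for the mean R-squared (default 0.9).
#' @param ... passed to [train_lm()].
#' @return object of class `topology_scan`: data.frame `scan` with columns
#'   `n_hidden`, `mean_r2`, `sd_r2`; `selected`; logical `plateau`.
#' @export
select_topology <- function(table, hidden_sizes = 1:15, n_repeats = 10,
                            n_inits = 10, seed = 1, plateau = 0.005,
                            r2_min = 0.9, ...) {
  hidden_sizes <- as.integer(hidden_sizes)
  if (length(hidden_sizes) == 0L) stop("'hidden_sizes' is empty", call. = FALSE)
  if (any(diff(hidden_sizes) <= 0)) {
    stop("'hidden_sizes' must be strictly increasing", call. = FALSE)
  }
  if (n_repeats < 1 || n_inits < 1) {
    stop("'n_repeats' and 'n_inits' must be at least 1", call. = FALSE)
  }
  mean_r2 <- sd_r2 <- numeric(length(hidden_sizes))
  for (s in seq_along(hidden_sizes)) {
    h <- hidden_sizes[s]
    bests <- vapply(seq_len(n_repeats), function(rep) {
      r2 <- vapply(seq_len(n_inits), function(init) {
        train_lm(table, n_hidden = h,
                 seed = derive_seed(seed, h, rep, init), ...)$r2
      }, numeric(1))
      max(r2)
    }, numeric(1))
    mean_r2[s] <- mean(bests)
    sd_r2[s] <- if (n_repeats > 1) sd(bests) else 0
  }
  ok <- mean_r2 >= r2_min
  gain <- c(diff(mean_r2), 0) # last size has no successor: counts as plateaued
  candidates <- which(ok & gain < plateau)
  if (length(candidates)) {
    selected <- hidden_sizes[candidates[1]]
    plateaued <- TRUE
  } else {
    selected <- hidden_sizes[which.max(mean_r2)]
    plateaued <- FALSE
  }
  structure(
    list(scan = data.frame(n_hidden = hidden_sizes, mean_r2 = mean_r2,
                           sd_r2 = sd_r2),
         selected = selected, plateau = plateaued,
         n_repeats = n_repeats, n_inits = n_inits, seed = as.integer(seed)),
    class = "topology_scan"
  )
}

#' @export
print.topology_scan <- function(x, ...) {
  cat("Hidden-layer scan (", x$n_repeats, " repeats x ", x$n_inits,
      " inits per size)\n", sep = "")
  print(x$scan, row.names = FALSE, digits = 4)
  cat("selected:", x$selected,
      if (x$plateau) "(plateau)" else "(no size reached the R2 level; argmax)",
      "\n")
  invisible(x)
}
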