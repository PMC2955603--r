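#' Build the regression design of one phase
#'
#' For a target gene and a phase `[start, end)` the response stacks the
#' target's values at times `start, ..., end - 1` over all series
#' (replicate/strain combinations); the design matrix pairs each response
#' row with an intercept column of ones and the parents' values at the
#' preceding time point in the same series. Rows containing a missing value
#' in any used cell are dropped.
#'
#' @param data A [as_tvn_expr()] dataset.
#' @param target Target gene id.
#' @param parents Character vector of parent gene ids (possibly empty).
#' @param phase Length-2 integer vector `c(start, end)` with
#'   `2 <= start < end <= n + 1`.
#' @return A list with elements `D` (rows x (s + 1) matrix, first column
#'   ones), `y` (response vector) and `dropped` (number of rows removed for
#'   missingness).
#' @examples
#' d <- as_tvn_expr(data.frame(
#'   gene = rep(c("t", "p"), each = 4), time = rep(1:4, 2),
#'   replicate = 1L, value = c(1, 2, 3, 4, 0.5, 0.6, 0.7, 0.8)
#' ))
#' phase_design(d, "t", "p", c(2, 4))
#' @export
phase_design <- function(data, target, parents, phase) {
  n <- attr(data, "n")
  start <- as.integer(phase[1]); end <- as.integer(phase[2])
  if (start < 2L || end > n + 1L || start >= end) {
    abort("phase bounds must satisfy 2 <= start < end <= n + 1",
          class = "tvn_domain_error")
  }
  arr <- expr_array(data)
  genes <- rownames(arr)
  if (!target %in% genes) abort("target gene not found", class = "tvn_domain_error")
  if (length(parents) && !all(parents %in% genes)) {
    abort("parent gene(s) not found", class = "tvn_domain_error")
  }
  times <- start:(end - 1L)
  n_series <- dim(arr)[3]
  # rows run time-fastest, then series (array flattening order)
  y <- as.numeric(arr[target, times, , drop = FALSE])
  D <- matrix(1, nrow = length(times) * n_series, ncol = 1L + length(parents))
  if (length(parents)) {
    for (j in seq_along(parents)) {
      D[, j + 1L] <- as.numeric(arr[parents[j], times - 1L, , drop = FALSE])
    }
  }
  keep <- complete.cases(cbind(D, y))
  dropped <- sum(!keep)
  if (!any(keep)) {
    abort(sprintf("phase [%d, %d) of gene %s has no complete rows", start, end, target),
          class = "tvn_domain_error")
  }
  D <- D[keep, , drop = FALSE]
  y <- y[keep]
  colnames(D) <- c("(intercept)", parents)
  list(D = D, y = y, dropped = dropped)
}
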