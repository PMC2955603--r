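#' Replicated time-course expression data
#'
#' The package's data container is a long tibble with one row per measured
#' value and columns `gene`, `time`, `replicate`, `strain` and `value`
#' (log-expression units). `strain` distinguishes genetic contexts in
#' knock-out designs; single-context (wild-type) data use the constant
#' `"WT"`. Every `gene` must be observed on the full `time x replicate x
#' strain` grid (missing measurements are `NA`).
#'
#' @param x A data frame with columns `gene`, `time`, `replicate`, `value`
#'   and optionally `strain`.
#' @return A tibble of class `tvn_expr` with attributes `n` (time points),
#'   `genes`, `replicates` and `strains`.
#' @examples
#' df <- expand.grid(gene = c("g1", "g2"), time = 1:4, replicate = 1:2)
#' df$value <- rnorm(nrow(df))
#' as_tvn_expr(df)
#' @export
as_tvn_expr <- function(x) {
  x <- tibble::as_tibble(x)
  needed <- c("gene", "time", "replicate", "value")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "tvn_domain_error")
  }
  if (!"strain" %in% names(x)) x$strain <- "WT"
  x <- dplyr::mutate(x,
    gene = as.character(.data$gene),
    time = as.integer(.data$time),
    replicate = as.integer(.data$replicate),
    strain = as.character(.data$strain),
    value = as.double(.data$value)
  )
  x <- dplyr::arrange(x, .data$gene, .data$strain, .data$replicate, .data$time)
  times <- sort(unique(x$time))
  n <- length(times)
  if (n < 3) abort("need at least 3 time points", class = "tvn_domain_error")
  if (!identical(times, seq_len(n))) {
    abort("`time` must cover 1..n contiguously", class = "tvn_domain_error")
  }
  genes <- unique(x$gene)
  reps <- sort(unique(x$replicate))
  strains <- unique(x$strain)
  expected <- n * length(reps) * length(strains)
  counts <- dplyr::count(x, .data$gene)
  if (any(counts$n != expected)) {
    bad <- counts$gene[counts$n != expected][1]
    abort(sprintf("gene %s is not observed on the full time x replicate x strain grid", bad),
          class = "tvn_domain_error")
  }
  if (any(is.infinite(x$value))) {
    abort("non-missing expression values must be finite", class = "tvn_domain_error")
  }
  structure(x,
    n = n, genes = genes, replicates = reps, strains = strains,
    class = c("tvn_expr", class(tibble::tibble()))
  )
}

#' Number of time points of an expression dataset
#' @param data A `tvn_expr` object.
#' @return Integer number of time points.
#' @export
n_times <- function(data) attr(data, "n")

# Dense array view: genes x times x series, where a series is one
# (strain, replicate) combination. Series order: strain-major.
expr_array <- function(data) {
  n <- attr(data, "n")
  genes <- attr(data, "genes")
  reps <- attr(data, "replicates")
  strains <- attr(data, "strains")
  series <- paste(rep(strains, each = length(reps)), rep(reps, length(strains)), sep = "/")
  arr <- array(NA_real_,
    dim = c(length(genes), n, length(series)),
    dimnames = list(genes, NULL, series)
  )
  idx_g <- match(data$gene, genes)
  idx_s <- match(paste(data$strain, data$replicate, sep = "/"), series)
  arr[cbind(idx_g, data$time, idx_s)] <- data$value
  arr
}

# Cumulative cross-products feeding the sampler.  For target gene i and
# candidate set C (size p), each lag-1 transition t (2..n) and series l
# yields a row z = (1, x_C(t-1, l), x_i(t, l)); rows with any NA across the
# full candidate panel or the target are dropped (complete-case).  Slice
# t - 1 of the returned cube is the sum of z z^T over transitions 2..t
# (slice 1 is zero), so any phase cross-product is a difference of two
# slices.
build_cross <- function(data, target, candidates) {
  arr <- expr_array(data)
  genes <- attr(data, "genes")
  if (!target %in% genes) {
    abort(sprintf("target gene %s not found", target), class = "tvn_domain_error")
  }
  missing_cand <- setdiff(candidates, genes)
  if (length(missing_cand)) {
    abort(paste0("candidate gene(s) not found: ", paste(missing_cand, collapse = ", ")),
          class = "tvn_domain_error")
  }
  n <- attr(data, "n")
  p <- length(candidates)
  q <- p + 2L
  n_series <- dim(arr)[3]
  cum <- array(0, dim = c(q, q, n))
  rows_cum <- numeric(n)
  xc <- arr[candidates, , , drop = FALSE]
  xt <- arr[target, , , drop = FALSE]
  for (t in 2:n) {
    # series x (1, candidates at t-1, target at t)
    Z <- cbind(1, t(matrix(xc[, t - 1L, ], nrow = p)), as.numeric(xt[1, t, ]))
    keep <- complete.cases(Z)
    M <- crossprod(Z[keep, , drop = FALSE])
    cum[, , t] <- cum[, , t - 1L] + M
    rows_cum[t] <- rows_cum[t - 1L] + sum(keep)
  }
  list(cum = cum, rows_cum = rows_cum, n = n, p = p,
       target = target, candidates = candidates,
       n_series = n_series)
}
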