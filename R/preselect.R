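#' Rank candidate regulators by windowed profile correlation
#'
#' For each candidate, the score is the maximum over all windows of
#' `window` successive time points of the absolute Pearson correlation
#' between the candidate's and the target's replicate-averaged expression
#' profiles. With `lag = 1` the candidate's window is shifted one time
#' point earlier than the target's, matching the lag-1 regression model;
#' the default `lag = 0` scores plain profile similarity. The `top`
#' highest-scoring candidates are returned.
#'
#' @param data A [as_tvn_expr()] dataset.
#' @param target Target gene id.
#' @param candidates Candidate gene ids; defaults to every other gene.
#' @param window Window length in time points.
#' @param top Number of candidates to return.
#' @param lag 0 (profile similarity) or 1 (lagged).
#' @return A tibble with columns `gene` and `score`, ranked by decreasing
#'   score, at most `top` rows.
#' @export
preselect_parents <- function(data, target, candidates = NULL,
                              window = 10, top = 10, lag = 0) {
  n <- attr(data, "n")
  stopifnot(lag %in% c(0, 1))
  if (n < window + lag) {
    abort("need at least `window + lag` time points", class = "tvn_domain_error")
  }
  candidates <- candidates %||% setdiff(attr(data, "genes"), target)
  prof <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(data), .data$gene, .data$time),
    value = mean(.data$value, na.rm = TRUE), .groups = "drop"
  )
  prof_of <- function(g) {
    v <- prof$value[prof$gene == g]
    v[order(prof$time[prof$gene == g])]
  }
  yt <- prof_of(target)
  starts <- seq_len(n - window - lag + 1L) + lag
  score_one <- function(g) {
    xc <- prof_of(g)
    cors <- vapply(starts, function(s) {
      a <- xc[(s - lag):(s - lag + window - 1L)]
      b <- yt[s:(s + window - 1L)]
      if (stats::sd(a, na.rm = TRUE) == 0 || stats::sd(b, na.rm = TRUE) == 0) {
        return(NA_real_)
      }
      abs(cor(a, b, use = "complete.obs"))
    }, numeric(1))
    if (all(is.na(cors))) {
      warn(sprintf("candidate %s has a constant profile in every window; scored 0", g))
      return(0)
    }
    max(cors, na.rm = TRUE)
  }
  scores <- tibble::tibble(
    gene = candidates,
    score = vapply(candidates, score_one, numeric(1), USE.NAMES = FALSE)
  )
  head(dplyr::arrange(scores, dplyr::desc(.data$score)), top)
}
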