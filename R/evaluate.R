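# Recovery metrics: positive predictive value and sensitivity for
# changepoints (exact integer position match) and for (parent, phase)
# edges restricted to exactly segmented genes.

truth_cps <- function(truth) {
  if (inherits(truth, "tvn_truth")) truth$changepoints else as.integer(truth)
}
selected_cps <- function(selected) {
  if (inherits(selected, "tvn_network")) selected$changepoints$position
  else as.integer(selected)
}

#' Changepoint recovery metrics
#'
#' True positives are inferred interior changepoints exactly matching true
#' positions (integer equality; `tolerance = 1` optionally allows a one
#' time-point offset, each true position matching at most one inferred
#' one). Sensitivity is `TP/(TP+FN)` and PPV `TP/(TP+FP)`, both on a
#' 0-100 scale; a ratio with zero denominator is undefined (`NA`), except
#' that sensitivity is 100 when there was nothing to find and nothing was
#' missed.
#'
#' @param truth A [sim_network()] structure or integer vector of true
#'   interior changepoints.
#' @param selected A [tvn_select()] network or integer vector of inferred
#'   positions.
#' @param tolerance 0 (exact, default) or 1.
#' @return A one-row tibble with `tp`, `fp`, `fn`, `sensitivity`, `ppv`.
#' @examples
#' eval_changepoints(c(5L, 9L), c(5L, 8L))
#' @export
eval_changepoints <- function(truth, selected, tolerance = 0) {
  tr <- truth_cps(truth)
  se <- selected_cps(selected)
  if (tolerance == 0) {
    tp <- length(intersect(tr, se))
  } else {
    used <- logical(length(se))
    tp <- 0L
    for (pos in tr) {
      hit <- which(!used & abs(se - pos) <= tolerance)
      if (length(hit)) {
        used[hit[1]] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- length(se) - tp
  fn <- length(tr) - tp
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else 100,
    ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  )
}

#' Edge recovery metrics on exactly segmented genes
#'
#' Edge recovery is only meaningful where the changepoint segmentation was
#' recovered exactly, so the phases of truth and selection coincide; for a
#' mis-segmented gene the result is flagged absent (`evaluated = FALSE`)
#' rather than scored. True positives are (parent, phase) pairs present in
#' both the generating structure and the selection.
#'
#' @param truth A [sim_network()] structure.
#' @param selected A [tvn_select()] network for the same gene.
#' @return A one-row tibble with `evaluated`, `tp`, `fp`, `fn`,
#'   `sensitivity`, `ppv`.
#' @export
eval_edges <- function(truth, selected) {
  tr <- truth_cps(truth)
  se <- selected_cps(selected)
  if (!identical(sort(as.integer(tr)), sort(as.integer(se)))) {
    return(tibble::tibble(evaluated = FALSE, tp = NA_integer_, fp = NA_integer_,
                          fn = NA_integer_, sensitivity = NA_real_, ppv = NA_real_))
  }
  true_edges <- paste(truth$edges$phase_index, truth$edges$parent)
  sel_edges <- if (nrow(selected$edges)) {
    paste(selected$edges$phase_index, selected$edges$parent)
  } else character(0)
  tp <- length(intersect(true_edges, sel_edges))
  fp <- length(sel_edges) - tp
  fn <- length(true_edges) - tp
  tibble::tibble(
    evaluated = TRUE, tp = tp, fp = fp, fn = fn,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else 100,
    ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  )
}
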