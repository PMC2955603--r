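# broom-style accessors for sampler traces, selected networks and
# generating structures.

#' @export
tidy.tvn_trace <- function(x, ...) x$draws

#' @export
glance.tvn_trace <- function(x, ...) {
  idx <- post_indices(x)
  acc <- x$acceptance
  rates <- setNames(
    as.list(ifelse(acc$proposed > 0, acc$accepted / acc$proposed, NA_real_)),
    paste0("accept_", acc$move)
  )
  tibble::tibble(
    target = x$target, iterations = x$iterations, burn_in = x$burn_in,
    mean_k = mean(x$draws$k[idx]),
    mean_delta2 = mean(x$draws$delta2[idx]),
    !!!rates
  )
}

#' @export
tidy.tvn_network <- function(x, ...) x$edges

#' @export
glance.tvn_network <- function(x, ...) {
  tibble::tibble(target = x$target, k = x$k,
                 n_edges = nrow(x$edges),
                 bf_threshold = x$bf_threshold)
}

#' @export
tidy.tvn_truth <- function(x, ...) {
  dplyr::left_join(x$edges, x$phases, by = "phase_index")
}

#' @export
glance.tvn_truth <- function(x, ...) {
  tibble::tibble(mode = x$mode, n = x$n, noise_sd = x$noise_sd,
                 k = length(x$changepoints), n_edges = nrow(x$edges))
}
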