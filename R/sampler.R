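#' Sample time-varying network structures for one target gene
#'
#' Runs the reversible-jump MCMC sampler for a single target gene against a
#' set of candidate regulators. Each iteration proposes one of four moves —
#' birth, death or shift of a changepoint, or an update (edge addition,
#' removal or exchange) of the regression model of one phase — and then
#' resamples the hyperparameters: the expected changepoint and parent
#' counts from their Gamma conditionals and the signal-to-noise ratio
#' `delta^2` by a Metropolis step. Regression coefficients and noise
#' variances are never sampled; they are marginalised analytically, so the
#' trace records only `(k, xi, Pa)` plus the hyperparameters.
#'
#' At a changepoint birth or death the parent sets of the affected phases
#' are re-proposed from the marginalised topology posterior restricted to
#' the new phase: exactly (by enumeration of all parent sets up to
#' `s_max`) when that space is small, otherwise from an independence
#' proposal whose inclusion odds derive from single-parent marginal
#' likelihood gains. Both branches compute the proposal density exactly, so
#' detailed balance holds either way.
#'
#' @param data A [as_tvn_expr()] dataset.
#' @param target Target gene id.
#' @param candidates Character vector of candidate regulators. The target
#'   may appear among them only with `allow_self = TRUE`.
#' @param iterations Number of MCMC iterations.
#' @param burn_in Fraction of iterations discarded by downstream summaries.
#' @param hyper A [tvn_hyper()] object.
#' @param seed Integer seed; when given, the run is exactly reproducible.
#' @param likelihood Internal switch: `FALSE` replaces the likelihood by a
#'   constant so the chain targets the prior (used for validation).
#' @param sample_hyper Resample `lambda`, `Lambda`, `delta2` along the
#'   chain? When `FALSE` they stay at their initial values in `hyper`.
#' @param delta2_update How the signal-to-noise ratio moves: by a
#'   Metropolis step on the marginalised score under its inverse-Gamma
#'   prior (`"mh"`, the default), refreshed from the inverse-Gamma
#'   distribution each sweep (`"prior"`), or held at its initial value
#'   (`"fixed"`).
#' @param allow_self Permit self-loops (target among candidates)?
#' @param enum_limit Maximum parent-set count for exact enumeration in
#'   birth/death proposals.
#' @return A `tvn_trace` object: a list with a `draws` tibble (iteration,
#'   k, move, accepted, lambda, Lambda, delta2), per-iteration changepoint
#'   vectors and parent-set masks, and run metadata.
#' @examples
#' truth <- sim_network(n_candidates = 2, phase_size = 12, seed = 1)
#' d <- sim_expression(truth, replicates = 2, seed = 1)
#' tr <- tvn_sample(d, truth$target, truth$candidates, iterations = 200, seed = 1)
#' tr
#' @export
tvn_sample <- function(data, target, candidates, iterations = 50000,
                       burn_in = 0.25, hyper = tvn_hyper(), seed = NULL,
                       likelihood = TRUE, sample_hyper = TRUE,
                       delta2_update = c("mh", "prior", "fixed"),
                       allow_self = FALSE, enum_limit = 64) {
  delta2_update <- match.arg(delta2_update)
  stopifnot(iterations >= 1, burn_in >= 0, burn_in < 1)
  if (!allow_self && target %in% candidates) {
    abort("target appears among candidates; set `allow_self = TRUE` to permit self-loops",
          class = "tvn_config_error")
  }
  n <- attr(data, "n")
  k_max <- resolve_kmax(hyper, n)
  p <- length(candidates)
  if (p < 1) abort("need at least one candidate regulator", class = "tvn_domain_error")
  cross <- build_cross(data, target, candidates)
  if (!is.null(seed)) set.seed(seed)
  opts <- list(
    iterations = as.integer(iterations), k_max = k_max,
    s_max = as.integer(hyper$s_max), enum_limit = as.integer(enum_limit),
    c = hyper$c, v_frac = hyper$v_frac,
    chi = hyper$chi, zeta = hyper$zeta, rho = hyper$rho,
    alpha = hyper$alpha, beta = hyper$beta,
    upsilon0 = hyper$upsilon0, gamma0 = hyper$gamma0,
    alpha_delta = hyper$alpha_delta, beta_delta = hyper$beta_delta,
    likelihood = isTRUE(likelihood), sample_hyper = isTRUE(sample_hyper),
    delta2_update = match(delta2_update, c("fixed", "mh", "prior")) - 1L,
    lambda_cp = hyper$lambda_cp, Lambda_par = hyper$Lambda_par,
    delta2 = hyper$delta2
  )
  res <- .run_chain(cross$cum, cross$rows_cum, n, p, opts)
  move_lab <- c("birth", "death", "shift", "update")
  draws <- tibble::tibble(
    iteration = seq_len(iterations),
    k = res$k,
    move = factor(move_lab[res$move], levels = move_lab),
    accepted = res$accepted,
    lambda = res$lambda,
    Lambda = res$Lambda,
    delta2 = res$delta2
  )
  acceptance <- tibble::tibble(
    move = factor(move_lab, levels = move_lab),
    proposed = res$proposed[1:4],
    accepted = res$accepted_n[1:4]
  )
  structure(
    list(
      draws = draws, cp = res$cp, pa_mask = res$pa,
      acceptance = acceptance,
      target = target, candidates = candidates,
      n = n, k_max = k_max, s_max_eff = min(hyper$s_max, p),
      iterations = as.integer(iterations),
      burn_in = as.integer(floor(burn_in * iterations)),
      seed = seed, hyper = hyper, cross = cross,
      likelihood = isTRUE(likelihood), sample_hyper = isTRUE(sample_hyper)
    ),
    class = "tvn_trace"
  )
}

# Indices of post-burn-in draws.
post_indices <- function(trace) {
  idx <- seq.int(trace$burn_in + 1L, trace$iterations)
  if (!length(idx)) abort("empty post-burn-in trace", class = "tvn_domain_error")
  idx
}

# Decode a vector of parent-set masks into a p x length(masks) logical
# matrix of inclusions (masks are exact doubles, p <= 52).
decode_masks <- function(masks, p) {
  out <- matrix(FALSE, nrow = p, ncol = length(masks))
  for (j in seq_len(p)) {
    out[j, ] <- (masks %/% 2^(j - 1)) %% 2 >= 1
  }
  out
}

#' @export
print.tvn_trace <- function(x, ...) {
  cat(sprintf("<tvn_trace> target %s, %d candidates, %d iterations (burn-in %d)\n",
              x$target, length(x$candidates), x$iterations, x$burn_in))
  post <- x$draws[post_indices(x), ]
  kt <- table(post$k)
  cat("  posterior over k: ",
      paste(sprintf("%s:%.2f", names(kt), as.numeric(kt) / nrow(post)), collapse = "  "),
      "\n", sep = "")
  ar <- x$acceptance
  cat("  acceptance: ",
      paste(sprintf("%s %.2f", ar$move, ifelse(ar$proposed > 0, ar$accepted / ar$proposed, NA)),
            collapse = "  "), "\n", sep = "")
  invisible(x)
}
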