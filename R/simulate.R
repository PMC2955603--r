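# Synthetic-data protocol: piecewise-constant lag-1 autoregressive targets
# driven by candidate regulators, in wild-type (multi-replicate time series)
# and knock-out (per-regulator deletion blocks) designs.

runif_signed <- function(m, lo = 0.1, hi = 2) {
  runif(m, lo, hi) * sample(c(-1, 1), m, replace = TRUE)
}

#' Draw a random time-varying regulatory structure
#'
#' Defines a ground-truth model for one target gene. The number of interior
#' changepoints is drawn uniformly between 0 and the largest count
#' compatible with `phase_size`, and their positions uniformly among the
#' configurations in which every phase spans at least `phase_size`
#' transitions (so `phase_size` is the *minimal* phase length;
#' `phase_size >= n - 1` forces a single phase). Each phase then receives a
#' random parent set of at most `max_edges` regulators, with coefficients
#' and intercept drawn uniformly from `[-2, -0.1] U [0.1, 2]`.
#'
#' @param n Number of time points.
#' @param n_candidates Number of candidate regulators.
#' @param phase_size Minimal phase length (transitions per phase).
#' @param max_edges Maximum parents per phase.
#' @param noise_sd Observation noise standard deviation carried by the
#'   structure for data generation.
#' @param mode `"wt"` or `"ko"` (determines the replication design of
#'   [sim_expression()]).
#' @param seed Integer seed.
#' @return A `tvn_truth` object: target/candidate ids, interior
#'   `changepoints`, a `phases` tibble and an `edges` tibble
#'   (phase_index, parent, coef), plus per-phase intercepts.
#' @examples
#' sim_network(n_candidates = 5, phase_size = 4, seed = 1)
#' @export
sim_network <- function(n = 12, n_candidates = 5, phase_size = 4,
                        max_edges = 5, noise_sd = 0.5,
                        mode = c("wt", "ko"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n >= 3, n_candidates >= 1, max_edges >= 1)
  if (phase_size < 1 || phase_size > n) {
    abort("`phase_size` must lie in 1..n", class = "tvn_domain_error")
  }
  if (!is.null(seed)) set.seed(seed)
  # phases partition the n - 1 transitions (times 2..n); each must span at
  # least phase_size of them
  k_feas <- max((n - 1L) %/% phase_size - 1L, 0L)
  k <- sample.int(k_feas + 1L, 1L) - 1L
  cps <- integer(0)
  if (k > 0) {
    for (tries in seq_len(100000)) {
      cand <- sort(sample(3:n, k))
      if (all(diff(c(2L, cand, n + 1L)) >= phase_size)) {
        cps <- cand
        break
      }
    }
    if (!length(cps)) {
      abort("could not place changepoints at this phase_size", class = "tvn_domain_error")
    }
  }
  bounds <- c(2L, cps, n + 1L)
  candidates <- sprintf("P%02d", seq_len(n_candidates))
  s_cap <- min(max_edges, n_candidates)
  phases <- tibble::tibble(
    phase_index = seq_len(k + 1),
    start = bounds[-length(bounds)],
    end = bounds[-1]
  )
  edges <- purrr::map_dfr(seq_len(k + 1), function(h) {
    s <- sample.int(s_cap, 1)
    pars <- sample(candidates, s)
    tibble::tibble(phase_index = h, parent = pars,
                   coef = runif_signed(s))
  })
  structure(
    list(
      n = n, mode = mode, noise_sd = noise_sd,
      target = "T01", candidates = candidates,
      changepoints = cps, phases = phases, edges = edges,
      intercepts = runif_signed(k + 1),
      max_edges = max_edges
    ),
    class = "tvn_truth"
  )
}

#' @export
print.tvn_truth <- function(x, ...) {
  cat(sprintf("<tvn_truth> %s design, n = %d, noise sd = %.2g\n",
              toupper(x$mode), x$n, x$noise_sd))
  cat("  changepoints: ",
      if (length(x$changepoints)) paste(x$changepoints, collapse = ", ") else "none",
      "\n", sep = "")
  cat(sprintf("  %d edge(s) across %d phase(s)\n", nrow(x$edges), nrow(x$phases)))
  invisible(x)
}

#' Generate expression data from a ground-truth structure
#'
#' Parent (regulator) values are drawn independently and uniformly from
#' `[-2, -0.1] U [0.1, 2]` for every time point of every replicate, and
#' the target follows the phase-specific lag-1 regression on them with
#' fresh `N(0, noise_sd^2)` noise — each replicate is one complete
#' realisation of the generating model.
#'
#' In the wild-type design a dataset holds the default 8 such replicates.
#' In the knock-out design each replicate contains one block per genetic
#' context — the unperturbed strain plus one deletion strain per candidate
#' regulator (default 4 replicates), each block an independent
#' realisation; within the deletion block of regulator `j` that
#' regulator's trajectory is 0, so its contribution to the target
#' vanishes there.
#'
#' @param truth A [sim_network()] structure.
#' @param replicates Replicates per time point; defaults to 8 (WT) or 4 (KO).
#' @param seed Integer seed.
#' @return A [as_tvn_expr()] dataset containing the target and all
#'   candidate regulators (KO data carry a `strain` column).
#' @examples
#' truth <- sim_network(seed = 1)
#' sim_expression(truth, seed = 2)
#' @export
sim_expression <- function(truth, replicates = NULL, seed = NULL) {
  stopifnot(inherits(truth, "tvn_truth"))
  if (!is.null(seed)) set.seed(seed)
  if (truth$mode == "wt") {
    replicates <- replicates %||% 8L
    as_tvn_expr(sim_block(truth, replicates, strain = "WT"))
  } else {
    replicates <- replicates %||% 4L
    strains <- c("WT", paste0("d", truth$candidates))
    blocks <- purrr::map2_dfr(
      strains, c(list(NULL), as.list(truth$candidates)),
      function(st, del) sim_block(truth, replicates, strain = st, drop_parent = del)
    )
    as_tvn_expr(blocks)
  }
}

# One genetic context: per-replicate parent redraw (zeroed for a deleted
# regulator), target via the phase-wise lag-1 regression plus noise.
sim_block <- function(truth, replicates, strain, drop_parent = NULL) {
  n <- truth$n
  p <- length(truth$candidates)
  coef_mat <- matrix(0, nrow = nrow(truth$phases), ncol = p,
                     dimnames = list(NULL, truth$candidates))
  for (r in seq_len(nrow(truth$edges))) {
    e <- truth$edges[r, ]
    coef_mat[e$phase_index, e$parent] <- e$coef
  }
  out <- vector("list", replicates)
  for (l in seq_len(replicates)) {
    xp <- matrix(runif_signed(p * n), nrow = p,
                 dimnames = list(truth$candidates, NULL))
    if (!is.null(drop_parent)) xp[drop_parent, ] <- 0
    xt <- numeric(n)
    xt[1] <- runif_signed(1)
    for (t in 2:n) {
      h <- sum(truth$changepoints <= t) + 1L
      xt[t] <- sum(coef_mat[h, ] * xp[, t - 1L]) + truth$intercepts[h] +
        rnorm(1, 0, truth$noise_sd)
    }
    out[[l]] <- tibble::tibble(
      gene = rep(c(truth$target, truth$candidates), each = n),
      time = rep(seq_len(n), p + 1L),
      replicate = l,
      strain = strain,
      value = c(xt, as.numeric(t(xp)))
    )
  }
  dplyr::bind_rows(out)
}
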