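#' Truncated Poisson probability mass function
#'
#' Poisson pmf with mean `mean`, renormalised over the support
#' `{0, ..., kmax}`; zero outside. Used as the prior both for the number of
#' changepoints (truncated at `k_max`) and for the number of parents in a
#' phase (truncated at `s_max`).
#'
#' @param k Integer count (vectorised).
#' @param mean Poisson mean, positive.
#' @param kmax Truncation point, non-negative integer.
#' @param log Return log probabilities?
#' @return Probabilities (or log probabilities) of the same length as `k`.
#' @examples
#' dtrunc_pois(0, mean = 1, kmax = 2) # 1 / (1 + 1 + 0.5)
#' @export
dtrunc_pois <- function(k, mean, kmax, log = FALSE) {
  stopifnot(mean > 0, kmax >= 0, kmax == round(kmax))
  if (any(k != round(k)) || any(k < 0)) {
    abort("`k` must contain non-negative integers", class = "tvn_domain_error")
  }
  support <- 0:kmax
  lw <- support * base::log(mean) - lgamma(support + 1)
  lz <- matrixStats_logsumexp(lw)
  lp <- ifelse(k <= kmax, k * base::log(mean) - lgamma(k + 1) - lz, -Inf)
  if (log) lp else exp(lp)
}

# Stable log-sum-exp for a numeric vector.
matrixStats_logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + base::log(sum(exp(x - m)))
}

#' Log prior of a changepoint position configuration
#'
#' Interior changepoints live on `{3, ..., n}` (the boundary points 2 and
#' `n + 1` are compulsory under the lag-1 model) and, given their number
#' `k`, every strictly increasing configuration is equally likely. The log
#' prior is therefore `-log choose(n - 2, k)`.
#'
#' @param positions Integer vector of interior changepoints (may be empty).
#' @param n Number of time points.
#' @return The log prior probability of the configuration.
#' @examples
#' log_prior_changepoints(integer(0), n = 12) # 0
#' log_prior_changepoints(7L, n = 12)         # -log(10)
#' @export
log_prior_changepoints <- function(positions, n) {
  positions <- validate_changepoints(positions, n)
  -lchoose(n - 2, length(positions))
}

# Shared validation: interior changepoints strictly increasing in {3..n}.
validate_changepoints <- function(positions, n, k_max = n - 2L) {
  if (n < 3) abort("need at least n = 3 time points", class = "tvn_domain_error")
  positions <- as.integer(positions)
  if (length(positions)) {
    if (any(positions < 3L | positions > n) ||
        any(duplicated(positions)) ||
        is.unsorted(positions, strictly = TRUE)) {
      abort("interior changepoints must be strictly increasing values in {3, ..., n}",
            class = "tvn_domain_error")
    }
  }
  if (length(positions) > k_max) {
    abort(sprintf("more changepoints (%d) than k_max (%d)", length(positions), k_max),
          class = "tvn_domain_error")
  }
  positions
}

#' Log prior of a parent set
#'
#' Given its size `s`, a parent set is uniform over all size-`s` subsets of
#' the candidate regulators, so the log prior is `-log choose(n_candidates, s)`.
#'
#' @param s Parent-set size.
#' @param n_candidates Number of candidate regulators.
#' @return Log prior probability.
#' @examples
#' log_prior_parents(2, 5) # -log(10)
#' @export
log_prior_parents <- function(s, n_candidates) {
  if (s < 0 || s != round(s) || s > n_candidates) {
    abort("`s` must be an integer in [0, n_candidates]", class = "tvn_domain_error")
  }
  -lchoose(n_candidates, s)
}

#' Move-type probabilities of the changepoint sampler
#'
#' At `k` current changepoints the sampler proposes a birth with probability
#' `b_k = c * min(1, p(k + 1) / p(k))` and a death with probability
#' `d_k = c * min(1, p(k - 1) / p(k))`, where `p` is the truncated Poisson
#' prior on the number of changepoints; `d_0 = v_0 = 0` and the birth
#' probability vanishes at `k_max`. The remaining mass is split between a
#' position shift (`v_frac` of it, when `k >= 1`) and a regression-model
#' update within one phase.
#'
#' @param k Current number of changepoints.
#' @param hyper A [tvn_hyper()] object.
#' @param k_max Truncation for the changepoint count prior.
#' @return A tibble with columns `k`, `birth`, `death`, `shift`, `update`
#'   summing to one.
#' @examples
#' move_probabilities(0, tvn_hyper(lambda_cp = 1), k_max = 5)
#' @export
move_probabilities <- function(k, hyper = tvn_hyper(), k_max) {
  stopifnot(k >= 0, k <= k_max)
  lam <- hyper$lambda_cp
  lp <- function(j) dtrunc_pois(j, lam, k_max, log = TRUE)
  b <- if (k < k_max) hyper$c * min(1, exp(lp(k + 1) - lp(k))) else 0
  d <- if (k > 0) hyper$c * min(1, exp(lp(k - 1) - lp(k))) else 0
  rem <- 1 - b - d
  v <- if (k > 0) hyper$v_frac * rem else 0
  w <- rem - v
  tibble::tibble(k = k, birth = b, death = d, shift = v, update = w)
}
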