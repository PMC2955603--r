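#' Hyperparameters for the time-varying network model
#'
#' Bundles every tunable prior and sampler constant. The number of interior
#' changepoints `k` follows a Poisson prior with mean `lambda_cp`, truncated
#' at `k_max`; the per-phase number of parents follows a Poisson with mean
#' `Lambda_par` truncated at `s_max`. Both means carry a Gamma(`alpha`,
#' scale = `beta`) hyperprior and are resampled along the chain, so
#' `lambda_cp` / `Lambda_par` act as initial values. Phase noise variances
#' carry an inverse-Gamma(`upsilon0`/2, `gamma0`/2) prior (the defaults give
#' a near-Jeffreys vague prior), and regression coefficients a zero-mean
#' Gaussian g-prior whose signal-to-noise scale `delta2` has an
#' inverse-Gamma(`alpha_delta`, `beta_delta`) hyperprior.
#'
#' Sampler constants: `c` is the maximal probability of proposing a
#' changepoint birth or death (must be below 1/4 so that shifts and
#' regression updates dominate); `v_frac` is the fraction of the remaining
#' move mass given to position shifts when at least one changepoint exists;
#' `chi`, `zeta`, `rho` split the regression update into edge addition,
#' removal and exchange and must sum to 1.
#'
#' @param lambda_cp Initial expected number of changepoints.
#' @param Lambda_par Initial expected number of parents per phase.
#' @param alpha,beta Shape and scale of the Gamma hyperprior on both means.
#' @param k_max Maximum number of changepoints; `NULL` means the maximal
#'   feasible value `n - 2` is filled in when a dataset is seen.
#' @param s_max Maximum number of parents per phase.
#' @param upsilon0,gamma0 Inverse-Gamma parameters (times 2) for the phase
#'   noise variance.
#' @param delta2 Initial signal-to-noise ratio of the coefficient g-prior.
#' @param alpha_delta,beta_delta Inverse-Gamma shape and scale for `delta2`.
#' @param c Move-probability constant, strictly below 1/4.
#' @param v_frac Fraction of non-birth/death mass allotted to shifts.
#' @param chi,zeta,rho Probabilities of edge addition, removal, exchange
#'   within a regression update; must sum to 1.
#'
#' @return An object of class `tvn_hyper` (a validated list).
#' @examples
#' h <- tvn_hyper()
#' h$c < 0.25
#' @export
tvn_hyper <- function(lambda_cp = 0.5, Lambda_par = 0.5,
                      alpha = 1, beta = 0.5,
                      k_max = NULL, s_max = 5,
                      upsilon0 = 1, gamma0 = 0.1,
                      delta2 = 1, alpha_delta = 2, beta_delta = 0.2,
                      c = 0.2, v_frac = 0.5,
                      chi = 0.4, zeta = 0.4, rho = 0.2) {
  stopifnot(
    lambda_cp > 0, Lambda_par > 0, alpha > 0, beta > 0,
    s_max >= 0, upsilon0 > 0, gamma0 > 0,
    delta2 > 0, alpha_delta > 0, beta_delta > 0,
    v_frac >= 0, v_frac <= 1,
    chi >= 0, zeta >= 0, rho >= 0
  )
  if (c >= 0.25) {
    abort("move constant `c` must be smaller than 1/4", class = "tvn_config_error")
  }
  if (abs(chi + zeta + rho - 1) > 1e-10) {
    abort("`chi + zeta + rho` must equal 1", class = "tvn_config_error")
  }
  if (!is.null(k_max)) stopifnot(k_max >= 0)
  structure(
    list(
      lambda_cp = lambda_cp, Lambda_par = Lambda_par,
      alpha = alpha, beta = beta,
      k_max = k_max, s_max = s_max,
      upsilon0 = upsilon0, gamma0 = gamma0,
      delta2 = delta2, alpha_delta = alpha_delta, beta_delta = beta_delta,
      c = c, v_frac = v_frac, chi = chi, zeta = zeta, rho = rho
    ),
    class = "tvn_hyper"
  )
}

# Resolve k_max against a dataset with n time points (k_max <= n - 2).
resolve_kmax <- function(hyper, n) {
  km <- hyper$k_max %||% (n - 2L)
  if (km > n - 2L) {
    abort(sprintf("k_max = %d exceeds the maximum n - 2 = %d", km, n - 2L),
          class = "tvn_config_error")
  }
  as.integer(km)
}

#' @export
print.tvn_hyper <- function(x, ...) {
  cat("<tvn_hyper>\n")
  cat(sprintf("  changepoints: lambda = %.3g (Ga(%.3g, %.3g) hyperprior), k_max = %s\n",
              x$lambda_cp, x$alpha, x$beta,
              if (is.null(x$k_max)) "n - 2" else x$k_max))
  cat(sprintf("  parents:      Lambda = %.3g, s_max = %d\n", x$Lambda_par, x$s_max))
  cat(sprintf("  noise:        sigma^2 ~ IG(%.3g/2, %.3g/2); delta^2 ~ IG(%.3g, %.3g), init %.3g\n",
              x$upsilon0, x$gamma0, x$alpha_delta, x$beta_delta, x$delta2))
  cat(sprintf("  moves:        c = %.3g, v_frac = %.3g, (chi, zeta, rho) = (%.3g, %.3g, %.3g)\n",
              x$c, x$v_frac, x$chi, x$zeta, x$rho))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
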