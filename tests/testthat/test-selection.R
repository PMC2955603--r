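# Posterior summaries, Bayes factors and the three-stage network
# selection.

make_trace <- function(seed = 1, iterations = 6000, noise_sd = 0.1) {
  # advance the seed until the structure has an interior changepoint so
  # stage-2 selection is exercised
  repeat {
    truth <- sim_network(n = 10, n_candidates = 3, phase_size = 4,
                         noise_sd = noise_sd, seed = seed)
    if (length(truth$changepoints) >= 1) break
    seed <- seed + 1
  }
  d <- sim_expression(truth, replicates = 4, seed = seed + 1)
  list(truth = truth,
       trace = tvn_sample(d, truth$target, truth$candidates,
                          iterations = iterations, seed = seed + 2))
}

test_that("posterior probabilities are empirical post-burn-in frequencies", {
  mt <- make_trace()
  tr <- mt$trace
  pk <- posterior_k(tr)
  expect_equal(sum(pk$prob), 1)
  for (kk in c(0, 1, 2)) {
    expect_equal(posterior_probability(tr, "k", kk), pk$prob[pk$k == kk])
  }
  # events true in every / no sample
  idx <- seq(tr$burn_in + 1, tr$iterations)
  always_k <- as.integer(names(which.max(table(tr$draws$k[idx]))))
  if (all(tr$draws$k[idx] == always_k)) {
    expect_equal(posterior_probability(tr, "k", always_k), 1)
  }
  expect_equal(posterior_probability(tr, "k", tr$k_max),
               mean(tr$draws$k[idx] == tr$k_max))
  pos <- posterior_positions(tr)
  expect_true(all(pos$prob >= 0 & pos$prob <= 1))
  # midpoint-rule parent frequencies match the generic event accessor,
  # and the exact-membership probabilities can never exceed them
  pp_mid <- posterior_parents(tr, 2, 7, method = "midpoint")
  expect_equal(
    posterior_probability(tr, "parent", tr$candidates[1], at = 4.5),
    pp_mid$prob[1]
  )
  pp_ex <- posterior_parents(tr, 2, 7, method = "exact")
  expect_true(all(pp_ex$prob <= pp_mid$prob + 1e-12))
})

test_that("bayes_factor follows the odds-ratio definition and labels", {
  expect_equal(bayes_factor(0.5, 0.5), 1)
  expect_equal(bayes_factor(0.9, 0.5), 9)
  expect_warning(bf <- bayes_factor(1, 0.5), "infinite")
  expect_identical(bf, Inf)
  expect_error(bayes_factor(0.5, 0), class = "tvn_domain_error")
  expect_error(bayes_factor(0.5, 1), class = "tvn_domain_error")
  expect_equal(bf_support(c(2.9, 3, 20, 21)),
               c("not supported", "positive", "positive", "strong"))
})

test_that("prior event probabilities match quadrature and symmetry", {
  h <- tvn_hyper()
  # P(k = 0) by integrating the truncated Poisson against the Gamma
  # hyperprior with adaptive quadrature
  k_max <- 10
  f <- Vectorize(function(lam) {
    dtrunc_pois(0, lam, k_max) * dgamma(lam, shape = 1, scale = 0.5)
  })
  pk0_quad <- integrate(f, 0, Inf, rel.tol = 1e-9)$value
  pk0_mc <- prior_event_probability("k", 0, h, n = 12, n_draws = 50000, seed = 4)
  # Rao-Blackwellised MC error at 5e4 draws is far below 3 sd of the plain
  # frequency estimator; 1% relative is conservative
  expect_equal(pk0_mc, pk0_quad, tolerance = 0.01)
  # probabilities over k sum to one
  pk <- vapply(0:k_max, function(kk) {
    prior_event_probability("k", kk, h, n = 12, n_draws = 5000, seed = 4)
  }, numeric(1))
  expect_equal(sum(pk), 1)
  # exchangeability: the parent-inclusion prior does not depend on the
  # candidate, only on the candidate count
  p1 <- prior_event_probability("parent", "a", h, n = 12, n_candidates = 5,
                                seed = 9)
  p2 <- prior_event_probability("parent", "b", h, n = 12, n_candidates = 5,
                                seed = 9)
  expect_identical(p1, p2)
})

test_that("selection returns the concentrated state and prunes monotonely", {
  mt <- make_trace(seed = 11, noise_sd = 0.05)
  net <- tvn_select(mt$trace)
  # near-noiseless: selection returns the generating structure
  expect_equal(net$changepoints$position, mt$truth$changepoints)
  expect_setequal(
    paste(net$edges$phase_index, net$edges$parent),
    paste(mt$truth$edges$phase_index, mt$truth$edges$parent)
  )
  # selected positions are exactly k, strictly increasing
  expect_equal(nrow(net$changepoints), net$k)
  expect_false(is.unsorted(net$changepoints$position, strictly = TRUE))
  # raising the threshold never adds parents
  net20 <- tvn_select(mt$trace, bf_threshold = 20)
  expect_true(all(
    paste(net20$edges$phase_index, net20$edges$parent) %in%
      paste(net$edges$phase_index, net$edges$parent)
  ))
  # coefficient signs match the generating coefficients
  joined <- merge(net$edges, mt$truth$edges,
                  by = c("phase_index", "parent"))
  expect_true(all(sign(joined$coef.x) == sign(joined$coef.y)))
})

test_that("selection is invariant to iteration order", {
  mt <- make_trace(seed = 21)
  tr <- mt$trace
  idx <- seq(tr$burn_in + 1, tr$iterations)
  set.seed(1)
  perm <- sample(idx)
  tr2 <- tr
  tr2$draws[idx, ] <- tr$draws[perm, ]
  tr2$cp[idx] <- tr$cp[perm]
  tr2$pa_mask[idx, ] <- tr$pa_mask[perm, ]
  n1 <- tvn_select(tr)
  n2 <- tvn_select(tr2)
  expect_equal(n1$changepoints, n2$changepoints)
  expect_equal(n1$edges, n2$edges)
})

test_that("tidiers expose draws and selected edges", {
  mt <- make_trace(seed = 31, iterations = 2000)
  td <- tidy(mt$trace)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2000)
  gl <- glance(mt$trace)
  expect_true(all(c("mean_k", "accept_update") %in% names(gl)))
  net <- tvn_select(mt$trace)
  expect_identical(tidy(net), net$edges)
  expect_equal(glance(net)$k, net$k)
  expect_s3_class(autoplot(mt$trace), "ggplot")
  expect_s3_class(autoplot(net), "ggplot")
})
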