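# The synthetic-data generator: structure geometry, coefficient support,
# the autoregressive data law, and the knock-out block design.

test_that("structure geometry respects the minimal phase length", {
  # single phase when phase_size = n (no room for an interior changepoint)
  tr12 <- sim_network(n = 12, phase_size = 12, seed = 1)
  expect_equal(tr12$changepoints, integer(0))
  expect_error(sim_network(n = 12, phase_size = 0), class = "tvn_domain_error")
  for (ps in c(1, 2, 4, 5)) {
    k_seen <- integer(0)
    for (sd_i in 1:25) {
      tr <- sim_network(n = 12, phase_size = ps, seed = sd_i * 7 + ps)
      lens <- diff(c(2L, tr$changepoints, 13L))
      expect_true(all(lens >= ps))
      # k bounded by feasibility: (n-1)/ps phases at most
      expect_lte(length(tr$changepoints), 11 %/% ps - 1)
      if (length(tr$changepoints)) {
        expect_true(all(tr$changepoints >= 3 & tr$changepoints <= 12))
        expect_false(is.unsorted(tr$changepoints, strictly = TRUE))
      }
      # phases tibble tiles [2, n+1)
      expect_equal(tr$phases$start, c(2L, tr$changepoints))
      expect_equal(tr$phases$end, c(tr$changepoints, 13L))
      k_seen <- c(k_seen, length(tr$changepoints))
    }
    # the changepoint count actually varies across series
    expect_gt(length(unique(k_seen)), 1)
  }
})

test_that("coefficients avoid (-0.1, 0.1) and edges are capped", {
  set.seed(2)
  for (i in 1:10) {
    tr <- sim_network(n = 12, n_candidates = 40, phase_size = 3,
                      max_edges = 5, seed = i)
    expect_true(all(abs(tr$edges$coef) >= 0.1 & abs(tr$edges$coef) <= 2))
    expect_true(all(abs(tr$intercepts) >= 0.1))
    per_phase <- table(tr$edges$phase_index)
    expect_true(all(per_phase <= 5))
    # parents unique within a phase
    expect_false(any(duplicated(paste(tr$edges$phase_index, tr$edges$parent))))
  }
})

test_that("noiseless wild-type data follow the regression law exactly", {
  truth <- sim_network(n = 12, n_candidates = 4, phase_size = 5,
                       noise_sd = 0, seed = 3)
  d <- sim_expression(truth, replicates = 3, seed = 4)
  arr <- tvdbn:::expr_array(d)
  coef_mat <- matrix(0, nrow(truth$phases), 4,
                     dimnames = list(NULL, truth$candidates))
  for (r in seq_len(nrow(truth$edges))) {
    coef_mat[truth$edges$phase_index[r], truth$edges$parent[r]] <-
      truth$edges$coef[r]
  }
  for (l in 1:3) {
    for (t in 2:12) {
      h <- sum(truth$changepoints <= t) + 1
      pred <- sum(coef_mat[h, ] * arr[truth$candidates, t - 1, l]) +
        truth$intercepts[h]
      expect_equal(unname(arr[truth$target, t, l]), pred)
    }
  }
  # default length and replication
  d8 <- sim_expression(truth, seed = 5)
  expect_equal(attr(d8, "n"), 12)
  expect_equal(length(attr(d8, "replicates")), 8)
  # reproducibility
  expect_identical(sim_expression(truth, seed = 6), sim_expression(truth, seed = 6))
})

test_that("knock-out blocks zero the deleted parent and only it", {
  truth <- sim_network(n = 8, n_candidates = 3, phase_size = 8,
                       noise_sd = 0, mode = "ko", seed = 7)
  d <- sim_expression(truth, replicates = 2, seed = 8)
  expect_setequal(unique(d$strain), c("WT", paste0("d", truth$candidates)))
  # deleted parent is zero within its own block, non-zero elsewhere
  for (cand in truth$candidates) {
    own <- d$value[d$gene == cand & d$strain == paste0("d", cand)]
    expect_true(all(own == 0))
    other <- d$value[d$gene == cand & d$strain == "WT"]
    expect_true(all(abs(other) >= 0.1))
  }
  # a target whose phase has a single parent reduces to the intercept in
  # that parent's deletion block (noiseless)
  truth1 <- sim_network(n = 6, n_candidates = 1, phase_size = 6,
                        noise_sd = 0, mode = "ko", seed = 9)
  d1 <- sim_expression(truth1, replicates = 1, seed = 10)
  del <- d1$value[d1$gene == truth1$target & d1$time > 1 &
                    d1$strain == paste0("d", truth1$candidates)]
  expect_equal(del, rep(truth1$intercepts[1], 5))
  # WT block minus deletion block isolates the parent contribution
  wt <- d1$value[d1$gene == truth1$target & d1$time > 1 & d1$strain == "WT"]
  par_wt <- d1$value[d1$gene == truth1$candidates & d1$time < 6 &
                       d1$strain == "WT"]
  expect_equal(wt - del, truth1$edges$coef[1] * par_wt)
})

test_that("default replication is 4 for knock-out data", {
  truth <- sim_network(n = 6, n_candidates = 2, phase_size = 6, mode = "ko",
                       seed = 11)
  d <- sim_expression(truth, seed = 12)
  expect_equal(length(attr(d, "replicates")), 4)
  expect_equal(length(attr(d, "strains")), 3)  # WT + one per regulator
})
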