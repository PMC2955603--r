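# Small datasets built in code.

# Deterministic toy dataset: `p` candidate genes plus one target, values
# from a fixed-seed draw; n time points, m replicates.
toy_dataset <- function(n = 5, m = 2, p = 2, seed = 42, noise_sd = 0.4) {
  set.seed(seed)
  genes <- c("tgt", paste0("c", seq_len(p)))
  df <- expand.grid(gene = genes, time = seq_len(n), replicate = seq_len(m),
                    stringsAsFactors = FALSE)
  df$value <- rnorm(nrow(df), sd = 1)
  # give the target some dependence on c1 after t = 3 so the posterior is
  # not flat
  arr <- df
  for (r in seq_len(m)) {
    for (t in 2:n) {
      i <- which(arr$gene == "tgt" & arr$time == t & arr$replicate == r)
      j <- which(arr$gene == "c1" & arr$time == t - 1 & arr$replicate == r)
      if (t >= 4) arr$value[i] <- 1.5 * arr$value[j] + rnorm(1, 0, noise_sd)
    }
  }
  as_tvn_expr(arr)
}

# Random small design matrices for marginal-likelihood checks.
random_design <- function(rows, s, seed) {
  set.seed(seed)
  D <- cbind(1, matrix(rnorm(rows * s), rows, s))
  y <- rnorm(rows)
  list(D = D, y = y)
}
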