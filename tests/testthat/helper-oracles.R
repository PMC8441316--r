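# Independent oracles used across the suite. These deliberately re-derive
# results from first principles (loops over definitions), not via the
# package code paths they check.

# Benjamini-Hochberg straight from the step-up definition:
# q_(i) = min over j >= i of n * p_(j) / j; reject iff q <= alpha.
bh_oracle <- function(p, alpha = 0.05) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    vals <- vapply(i:n, function(j) n * p[o][j] / j, numeric(1))
    q_sorted[i] <- min(1, min(vals))
  }
  q <- numeric(n)
  q[o] <- q_sorted
  list(q_values = q, reject = q <= alpha)
}

# Exact null of the size-m subset mean by explicit enumeration; the
# complete enumeration is the null distribution itself, so its spread is
# the population sd.
subset_mean_null_oracle <- function(z, m) {
  idx <- utils::combn(length(z), m)
  means <- numeric(ncol(idx))
  for (j in seq_len(ncol(idx))) means[j] <- mean(z[idx[, j]])
  mu <- sum(means) / length(means)
  sdv <- sqrt(sum((means - mu)^2) / length(means))
  list(mean = mu, sd = sdv)
}

# Upper-tail hypergeometric by enumerating every distinguishable draw.
hyper_oracle <- function(n_hit_flagged, n_hits, n_bg_flagged, n_bg) {
  total <- choose(n_bg, n_hits)
  prob_ge <- 0
  for (k in n_hit_flagged:min(n_hits, n_bg_flagged)) {
    prob_ge <- prob_ge +
      choose(n_bg_flagged, k) * choose(n_bg - n_bg_flagged, n_hits - k) /
      total
  }
  prob_ge
}

# Minimal cohort with exact group means and a little jitter for the t-test.
toy_cohort <- function(young_vals, old_vals, genes = NULL, jitter = 0) {
  n_genes <- nrow(young_vals)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(n_genes))
  m <- cbind(young_vals, old_vals)
  if (jitter > 0) m <- m + matrix(jitter * stats::rnorm(length(m)),
                                  nrow = n_genes)
  donors <- sprintf("d%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, donors)
  bracket <- rep(c("20s", "70s"), c(ncol(young_vals), ncol(old_vals)))
  expression_cohort(pmax(m, 0), tissue = "toy",
                    brackets = data.frame(donor = donors, bracket = bracket,
                                          midpoint = ifelse(bracket == "20s",
                                                            25, 75)))
}
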