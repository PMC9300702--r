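# Independent oracles used across the suite.

# Benjamini-Hochberg step-up by direct enumeration over ranks:
# q_(i) = min_{j >= i} p_(j) * n / j, mapped back to input order.
bh_brute_force <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(n)
  for (i in seq_len(n))
    q_sorted[i] <- min(1, min(ps[i:n] * n / (i:n)))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# upper-tail hypergeometric P(X >= k) by brute-force summation
hyper_tail_brute <- function(k, N, K, n) {
  xs <- k:min(K, n)
  xs <- xs[xs >= max(0, n - (N - K))]
  if (length(xs) == 0) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# two-sided one-sample t p value via stats::t.test (independent route)
ttest_oracle_p <- function(x) stats::t.test(x, mu = 0)$p.value

# rejection-sampling oracle for the observed-intensity distribution of
# background proteins under logistic dropout
rejection_sample_observed <- function(n, mean, sd_total, midpoint, slope,
                                      seed) {
  set.seed(seed)
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mean, sd_total)
    keep <- runif(2 * n) < plogis(slope * (x - midpoint))
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

# a single-cell FRAP trace assembled by hand
make_trace <- function(pre, post, dt = 1) {
  n_pre <- length(pre); n_post <- length(post)
  data.frame(cell_id = "c1",
             frame = seq_len(n_pre + n_post),
             time_s = (seq_len(n_pre + n_post) - 1) * dt,
             intensity = c(pre, post),
             phase = rep(c("pre", "post"), c(n_pre, n_post)),
             stringsAsFactors = FALSE)
}

# synthetic stand-in for a published pair of interactor ID lists with a
# prescribed set structure: n_a only in A, n_b only in B, n_shared in both
make_set_pair <- function(n_a_only, n_b_only, n_shared) {
  shared <- sprintf("SH%03d", seq_len(n_shared))
  list(a = c(sprintf("SA%03d", seq_len(n_a_only)), shared),
       b = c(sprintf("SB%03d", seq_len(n_b_only)), shared))
}
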