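# Independent brute-force oracles, written from the definitions and kept
# free of any package internals.

# BH step-up from the minimax definition:
# adj_p(i) = min over j with p_j >= p_i of min(1, m * p_j / rank(p_j)),
# with ties sharing the largest qualifying rank.
brute_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    cand <- which(p >= p[i])
    min(1, min(m * p[cand] / r[cand]))
  }, numeric(1))
}

# Literal two-stage step-up: stage-1 BH pass at q/(1+q) counts rejections
# r1; stage 2 reruns the step-up at q/(1+q) * m/(m - r1).
brute_step_up <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= alpha * seq_len(m) / m)
  r <- if (length(ok)) max(ok) else 0L
  if (r == 0L) rep(FALSE, m) else p <= ps[r]
}

brute_bky <- function(p, q) {
  m <- length(p)
  q1 <- q / (1 + q)
  r1 <- sum(brute_step_up(p, q1))
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  brute_step_up(p, q1 * m / (m - r1))
}

# Pseudo fold change by direct enumeration of the imputation rule.
brute_pseudo_fc <- function(observed_means, pool, quantile = 0.10,
                            missing_is_control = TRUE) {
  k <- max(1, ceiling(quantile * length(pool)))
  impute <- mean(sort(pool)[1:k])
  fc <- if (missing_is_control) observed_means - impute
        else impute - observed_means
  median(fc)
}

# Two-sample permutation p-value for the difference of means (two-sided).
brute_permutation_p <- function(a, b, n_perm = 10000, seed = 1) {
  set.seed(seed)
  pooled <- c(a, b)
  n1 <- length(a)
  obs <- abs(mean(a) - mean(b))
  hits <- replicate(n_perm, {
    idx <- sample.int(length(pooled), n1)
    abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-12
  })
  mean(hits)
}
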