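# Independent Mann-Whitney oracle: enumerate every split of the combined
# sample and count U by direct pair comparison (no ranks).
brute_force_zero_test <- function(y) {
  n <- length(y)
  combined <- c(y, rep(0, n))
  u_stat <- function(g1, g2) {
    sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  }
  idx <- combn(2 * n, n)
  EU <- n * n / 2
  u_obs <- u_stat(y, rep(0, n))
  u_all <- apply(idx, 2, function(i) u_stat(combined[i], combined[-i]))
  mean(abs(u_all - EU) >= abs(u_obs - EU) - 1e-9)
}

# literal step-up procedure: reject H_i at level a if p_i is among the first
# k ordered p-values where k = max{j : p_(j) <= a j / m}; the BH q-value is
# the smallest candidate level at which the gene is rejected
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  stepup_rejects <- function(a) {
    ps <- p[o]
    k <- which(ps <= a * seq_len(m) / m + 1e-12)
    if (!length(k)) return(logical(m))
    p <= ps[max(k)] + 1e-15
  }
  cand <- sort(unique(pmin(1, p[o] * m / seq_len(m))))
  q <- rep(1, m)
  for (i in seq_len(m)) {
    hit <- cand[vapply(cand, function(a) stepup_rejects(a)[i], logical(1))]
    if (length(hit)) q[i] <- min(hit)
  }
  q
}
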