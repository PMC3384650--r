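# Independent oracles the tests check the implementation against. These are
# deliberately naive (loops, direct enumeration) and share no code with the
# package internals.

# Topological overlap by triple loop over the stated formula.
tom_brute_force <- function(a) {
  n <- nrow(a)
  out <- matrix(0, n, n, dimnames = dimnames(a))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

# Upper hypergeometric tail P(X >= k) by direct enumeration with choose().
hyper_tail_oracle <- function(k, N, K, m) {
  xs <- k:min(K, m)
  sum(exp(lchoose(K, xs) + lchoose(N - K, m - xs) - lchoose(N, m)))
}

# One-sided (greater) Fisher exact p for a 2x2 table by summing over all
# tables with the observed margins and first cell >= observed.
fisher_greater_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  xs <- a:min(r1, c1)
  sum(choose(r1, xs) * choose(r2, c1 - xs)) / choose(n, c1)
}

# Exact binomial upper tail P(X >= k) by term-wise summation.
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  xs <- k:n
  sum(choose(n, xs) * p^xs * (1 - p)^(n - xs))
}

# Benjamini-Hochberg step-up transform, written out directly.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Leading right-singular direction of a standardized module submatrix by
# power iteration on the sample-space Gram matrix.
eigengene_power_iteration <- function(sub, iters = 1000) {
  sub <- t(scale(t(sub)))
  S <- crossprod(sub)
  v <- rep(1 / sqrt(ncol(sub)), ncol(sub))
  for (i in seq_len(iters)) {
    v <- S %*% v
    v <- v / sqrt(sum(v^2))
  }
  as.numeric(v)
}
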