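# Independent brute-force oracles shared by module and acceptance tests.

# numerical-integration oracle for the two-tailed Student t p-value
t_pvalue_oracle <- function(t, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(t), Inf, rel.tol = 1e-10)$value
}

# literal step-up definition: p_(i) adjusted = min_{j >= i} min(m p_(j)/j, 1)
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[o[i]] <- min(1, min(m * p[o[i:m]] / (i:m)))
  }
  adj
}

# direct transcription of the stability measure for an oracle
genorm_oracle <- function(counts) {
  l2 <- log2(counts)
  g <- nrow(counts)
  sapply(seq_len(g), function(j) {
    mean(sapply(setdiff(seq_len(g), j), function(k)
      sd(l2[j, ] - l2[k, ])))
  })
}

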