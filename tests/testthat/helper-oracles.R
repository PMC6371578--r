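# Independent brute-force oracles used to cross-check the package's
# statistics.  These deliberately re-derive each quantity from first
# principles and never call the functions they check.

# BH step-up by literal enumeration of the rule
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * p[ord[j]] / j, 0)
    q[ord[i]] <- min(1, min(cand))
  }
  q
}

# linear-interpolation quantile, h = (n - 1) q convention, by hand
quantile_oracle <- function(x, q) {
  s <- sort(x)
  h <- (length(s) - 1) * q
  lo <- floor(h)
  if (lo == length(s) - 1) return(s[length(s)])
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

# closed-form Pearson chi-square for a 2x2 table
chisq_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# AUC by exhaustive concordant-pair counting, ties counted 1/2
auc_oracle <- function(case, ctrl) {
  tot <- 0
  for (x in case) for (y in ctrl)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(case) * length(ctrl))
}

# pooled-variance two-sample t by the textbook formula
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}
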