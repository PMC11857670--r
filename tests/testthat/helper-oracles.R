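# Brute-force oracles shared by the unit and acceptance suites. These stay
# independent of the package implementations they check.

auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

tss_oracle <- function(labels, scores) {
  best <- -Inf; best_t <- NA
  for (t in sort(unique(scores))) {
    pred <- scores >= t
    v <- sum(pred & labels == 1) / sum(labels == 1) +
      sum(!pred & labels == 0) / sum(labels == 0) - 1
    if (v > best) { best <- v; best_t <- t }
  }
  list(tss = best, threshold = best_t)
}

# VIF by a route independent of the package's lm.fit path: the diagonal of
# the inverse sample correlation matrix
vif_oracle <- function(m) diag(solve(stats::cor(m)))
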