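# Independent oracles used across tests; deliberately naive implementations.

# brute-force variation from the printed formula, no shared code path
brute_variation <- function(v) {
  hi <- -Inf
  lo <- Inf
  for (x in v) {
    if (x > hi) hi <- x
    if (x < lo) lo <- x
  }
  100 * (hi - lo) / ((hi + lo) / 2)
}

# pairwise-enumeration AUC with half credit for ties
brute_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) {
    if (p > q) s <- s + 1
    else if (p == q) s <- s + 0.5
  }
  s / (length(pos) * length(neg))
}

# closed-form binormal AUC
binormal_auc <- function(mu1, sd1, mu0, sd0) {
  pnorm((mu1 - mu0) / sqrt(sd1^2 + sd0^2))
}

# two-group normal scores under a fixed configuration
binormal_scores <- function(n1, n0, mu1, sd1, mu0, sd0) {
  list(scores = c(rnorm(n1, mu1, sd1), rnorm(n0, mu0, sd0)),
       labels = rep(c(TRUE, FALSE), c(n1, n0)))
}
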