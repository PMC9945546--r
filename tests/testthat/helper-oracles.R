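# Independent brute-force oracles shared by the evaluation and acceptance tests.

auc_bruteforce <- function(scores, labels) {
  p <- scores[labels == 1]; b <- scores[labels == 0]
  wins <- 0
  for (x in p) wins <- wins + sum(x > b) + 0.5 * sum(x == b)
  wins / (length(p) * length(b))
}

threshold_bruteforce <- function(scores, labels, rule) {
  pres <- scores[labels == 1]; bg <- scores[labels == 0]
  cand <- c(-Inf, sort(unique(scores)), Inf)
  best <- NULL; best_crit <- Inf
  for (t in cand) {
    sens <- mean(pres >= t); spec <- mean(bg < t)
    crit <- switch(rule,
                   SensEqSpec = abs(sens - spec),
                   MaxSensSpec = -(sens + spec),
                   MinROCdist = sqrt((1 - sens)^2 + (1 - spec)^2))
    if (crit < best_crit) { best_crit <- crit; best <- t }
  }
  best
}

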