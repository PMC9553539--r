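# Independent oracles used by the mRMR tests: a from-scratch plug-in
# mutual-information estimator and a brute-force greedy mRMR ranker, both
# written as direct loops over the definitions (no shared code with the
# implementation under test).

oracle_mi <- function(x, y) {
  n <- length(x)
  total <- 0
  for (xv in unique(x)) {
    for (yv in unique(y)) {
      pxy <- sum(x == xv & y == yv) / n
      if (pxy > 0) {
        px <- sum(x == xv) / n
        py <- sum(y == yv) / n
        total <- total + pxy * log2(pxy / (px * py))
      }
    }
  }
  total
}

oracle_entropy <- function(x) {
  n <- length(x)
  h <- 0
  for (xv in unique(x)) {
    p <- sum(x == xv) / n
    h <- h - p * log2(p)
  }
  h
}

oracle_discretize <- function(x, alpha = 1) {
  s <- sqrt(sum((x - mean(x))^2) / length(x))   # population sd
  if (is.na(s) || s == 0) return(rep(0L, length(x)))
  lo <- mean(x) - alpha * s
  hi <- mean(x) + alpha * s
  ifelse(x <= lo, -1L, ifelse(x >= hi, 1L, 0L))
}

# Brute-force greedy MID/MIQ ranking evaluating the criterion of every
# candidate at every step from scratch.
oracle_mrmr <- function(X, y, scheme = "MID", alpha = 1, eps = 1e-12) {
  p <- ncol(X)
  D <- matrix(0L, nrow(X), p)
  for (j in seq_len(p)) D[, j] <- oracle_discretize(X[, j], alpha)
  rel <- vapply(seq_len(p), function(j) oracle_mi(D[, j], y), numeric(1))
  selected <- integer(0)
  candidates <- seq_len(p)
  while (length(candidates)) {
    crit <- vapply(candidates, function(j) {
      if (!length(selected)) return(rel[j])
      r <- mean(vapply(selected, function(s) oracle_mi(D[, j], D[, s]),
                       numeric(1)))
      if (scheme == "MID") rel[j] - r else rel[j] / max(r, eps)
    }, numeric(1))
    best <- candidates[which.max(crit)]
    selected <- c(selected, best)
    candidates <- setdiff(candidates, best)
  }
  selected
}

# Per-step criterion certificate: TRUE when every greedy pick scores at
# least as high as every candidate left at that step.
oracle_mrmr_certificate <- function(order, X, y, scheme = "MID", alpha = 1,
                                    eps = 1e-12, tol = 1e-12) {
  p <- ncol(X)
  D <- matrix(0L, nrow(X), p)
  for (j in seq_len(p)) D[, j] <- oracle_discretize(X[, j], alpha)
  rel <- vapply(seq_len(p), function(j) oracle_mi(D[, j], y), numeric(1))
  crit_of <- function(j, selected) {
    if (!length(selected)) return(rel[j])
    r <- mean(vapply(selected, function(s) oracle_mi(D[, j], D[, s]),
                     numeric(1)))
    if (scheme == "MID") rel[j] - r else rel[j] / max(r, eps)
  }
  for (step in seq_len(p)) {
    selected <- order[seq_len(step - 1L)]
    remaining <- setdiff(seq_len(p), selected)
    chosen <- crit_of(order[step], selected)
    for (j in remaining) {
      if (crit_of(j, selected) > chosen + tol) return(FALSE)
    }
  }
  TRUE
}
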