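# Independent brute-force oracles used by the property and acceptance
# tests. Each is written as a direct transcription of the defining
# condition, separate from the package's algorithms.

# every contiguous 2-partition of the sorted distinct counts, scored by
# within-group sum of squares; returns the minimum and all argmins
oracle_contiguous_split <- function(counts) {
  x <- sort(unique(as.integer(counts)))
  best <- Inf
  argmins <- list()
  for (cut in seq_len(length(x) - 1L)) {
    lo <- x[seq_len(cut)]
    hi <- x[-seq_len(cut)]
    wss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (wss < best - 1e-12) {
      best <- wss
      argmins <- list(list(low = lo, high = hi))
    } else if (abs(wss - best) <= 1e-12) {
      argmins <- c(argmins, list(list(low = lo, high = hi)))
    }
  }
  list(wss = best, partitions = argmins)
}

split_wss <- function(sp) {
  sum((sp$low - mean(sp$low))^2) + sum((sp$high - mean(sp$high))^2)
}

# exhaustive stretch enumeration: every index window, the qualifying
# predicate re-evaluated from its definition, reduced to maximal
# windows, overlapping maximal windows reduced to the longest
oracle_stretches <- function(positions, min_n, min_density) {
  n <- length(positions)
  qualifies <- function(i, j) {
    cnt <- j - i + 1
    if (cnt < min_n) return(FALSE)
    span <- positions[j] - positions[i]
    if (span == 0) return(TRUE)
    cnt / (span / 1000) >= min_density
  }
  wins <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!qualifies(i, j)) next
      left <- i > 1 && qualifies(i - 1, j)
      right <- j < n && qualifies(i, j + 1)
      if (!left && !right) wins[[length(wins) + 1L]] <- c(i, j)
    }
  }
  if (!length(wins)) {
    return(data.frame(start = integer(), end = integer(), n = integer()))
  }
  w <- do.call(rbind, wins)
  w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
  groups <- list()
  g <- w[1, , drop = FALSE]
  gend <- w[1, 2]
  for (r in seq_len(nrow(w))[-1]) {
    if (w[r, 1] <= gend) {
      g <- rbind(g, w[r, ])
      gend <- max(gend, w[r, 2])
    } else {
      groups[[length(groups) + 1L]] <- g
      g <- w[r, , drop = FALSE]
      gend <- w[r, 2]
    }
  }
  groups[[length(groups) + 1L]] <- g
  do.call(rbind, lapply(groups, function(g) {
    span <- positions[g[, 2]] - positions[g[, 1]]
    cnt <- g[, 2] - g[, 1] + 1
    k <- order(-span, -cnt, g[, 1])[1]
    data.frame(start = positions[g[k, 1]], end = positions[g[k, 2]],
               n = cnt[k])
  }))
}

# exact hypergeometric two-sided p over all tables with the observed
# margins, point probabilities via plain choose()
oracle_fisher_p <- function(a, r1, r2, c1) {
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Spearman rank correlation by the textbook no-ties formula
oracle_spearman <- function(a, b) {
  d <- rank(a) - rank(b)
  n <- length(a)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
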