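# Independent brute-force oracles used to validate the package's metric
# implementations. Kept deliberately naive: exhaustive enumeration, no
# shared code with the implementations under test.

# Harrell's C by exhaustive pair counting via outer() on ordered pairs.
oracle_cindex <- function(scores, times, events) {
  n <- length(scores)
  comparable <- outer(seq_len(n), seq_len(n), function(i, j) {
    (events[i] == 1) & (i != j) &
      (times[i] < times[j] |
         (times[i] == times[j] & events[j] == 0))
  })
  better <- outer(scores, scores, ">")
  tied <- outer(scores, scores, "==")
  num <- sum(comparable & better) + 0.5 * sum(comparable & tied)
  num / sum(comparable)
}

# AUROC by exhaustive case-control pair counting.
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  gt <- sum(outer(pos, neg, ">"))
  eq <- sum(outer(pos, neg, "=="))
  (gt + 0.5 * eq) / (length(pos) * length(neg))
}

# Hypergeometric upper tail by enumerating every possible draw of the
# query-sized subset from the universe.
oracle_hypergeom <- function(query_size, target_size, universe_size,
                             observed) {
  draws <- utils::combn(universe_size, query_size)
  in_target <- draws <= target_size      # wlog target = first elements
  mean(colSums(in_target) >= observed)
}

# Benjamini-Hochberg step-up by hand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Two-group log-rank chi-square from the O - E / V hypergeometric formula,
# computed at each distinct event time.
oracle_logrank <- function(times, events, group) {
  group <- as.integer(factor(group))
  stopifnot(all(group %in% 1:2))
  ev_times <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n - d) / (n - 1) * n1 * (n - n1) / n^2
  }
  (O1 - E1)^2 / V
}

# Adjusted Rand index between two label vectors.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_comb - expected) / ((sum_a + sum_b) / 2 - expected)
}
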