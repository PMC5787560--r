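# Independent oracles used to check the fast implementations.

# Exhaustive enumeration of all monotone warping paths (with optional band),
# minimal total |x_i - y_j| cost. Only tractable for short series.
dtw_oracle <- function(x, y, band = Inf) {
  n <- length(x); m <- length(y)
  best <- Inf
  rec <- function(i, j, cost) {
    if (abs(i - j) > band) return(invisible())
    cost <- cost + abs(x[i] - y[j])
    if (cost >= best) return(invisible())
    if (i == n && j == m) {
      best <<- cost
      return(invisible())
    }
    if (i < n) rec(i + 1L, j, cost)
    if (j < m) rec(i, j + 1L, cost)
    if (i < n && j < m) rec(i + 1L, j + 1L, cost)
  }
  rec(1L, 1L, 0)
  best
}

# Mann-Whitney U by explicit pair counting with midrank ties.
u_statistic_oracle <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Expected richness when drawing `d` reads without replacement from counts
# (sum over taxa of the probability at least one read is drawn).
expected_richness <- function(counts, d) {
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, d) - lchoose(N, d)))
}

# Pearson correlation from the textbook covariance formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Two-term Kullback-Leibler evaluation of the Jensen-Shannon divergence.
jsd_oracle <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log(a[i]) - log(b[i])))
  }
  (kl(p, m) + kl(q, m)) / 2
}
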