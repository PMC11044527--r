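# Independent brute-force oracles used by the unit and acceptance tests.
# These enumerate permutation distributions directly (combn / expand.grid)
# and never call the package's DP-based exact routines.

perm_p_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  obs <- abs(sum(r[seq_len(n1)]) - n1 * (length(pooled) + 1) / 2)
  combos <- utils::combn(length(pooled), n1)
  stats <- apply(combos, 2, function(idx) {
    abs(sum(r[idx]) - n1 * (length(pooled) + 1) / 2)
  })
  mean(stats >= obs - 1e-12)
}

perm_p_kruskal <- function(groups) {
  x <- unlist(groups)
  nj <- lengths(groups)
  N <- length(x)
  r <- rank(x)
  H_of <- function(assign) {
    Rj <- tapply(r, assign, sum)
    12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  }
  obs <- H_of(rep(seq_along(groups), nj))
  idx1 <- utils::combn(N, nj[1])
  total <- 0
  hit <- 0
  for (i in seq_len(ncol(idx1))) {
    rest1 <- setdiff(seq_len(N), idx1[, i])
    idx2 <- utils::combn(length(rest1), nj[2])
    for (j in seq_len(ncol(idx2))) {
      g2 <- rest1[idx2[, j]]
      g3 <- setdiff(rest1, g2)
      assign <- integer(N)
      assign[idx1[, i]] <- 1L
      assign[g2] <- 2L
      assign[g3] <- 3L
      total <- total + 1
      if (H_of(assign) >= obs - 1e-12) hit <- hit + 1
    }
  }
  hit / total
}

perm_p_wilcoxon <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  mu <- n * (n + 1) / 4
  obs <- abs(sum(r[d > 0]) - mu)
  signs <- expand.grid(rep(list(c(0, 1)), n))
  stats <- apply(signs, 1, function(s) abs(sum(r[s == 1]) - mu))
  mean(stats >= obs - 1e-12)
}


# Analytic minimum of a two-component normal mixture density on a fine
# grid (independent oracle for trough placement).
mixture_min <- function(w1, m1, s1, w2, m2, s2) {
  xs <- seq(m1, m2, by = 1e-4)
  dens <- w1 * dnorm(xs, m1, s1) + w2 * dnorm(xs, m2, s2)
  xs[which.min(dens)]
}


# Midranks built from sorting alone (independent of base rank()).
midrank_oracle <- function(v) {
  o <- order(v)
  r <- numeric(length(v))
  i <- 1
  while (i <= length(v)) {
    j <- i
    while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}
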