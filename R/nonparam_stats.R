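# Rank-based tests with SPSS-style reporting: midranks for ties, the
# standard tie-correction terms in the asymptotic variances, no continuity
# correction, two-sided p-values, and per-group mean ranks alongside the
# statistic. Like SPSS, small samples additionally get an exact
# permutation p-value (computed by dynamic programming over the
# permutation distribution, or full enumeration for Kruskal-Wallis); the
# asymptotic Z/chi-square is always reported.

stat_result <- function(test, statistic, statistic_name, z = NA_real_,
                        df = NA_real_, p_value = NA_real_,
                        mean_ranks = numeric(0), n = integer(0),
                        flags = character(0), p_method = "asymptotic") {
  structure(
    list(test = test, statistic = statistic,
         statistic_name = statistic_name, z = z, df = df,
         p_value = p_value, p_method = p_method,
         mean_ranks = mean_ranks, n = n, flags = flags),
    class = "stat_result"
  )
}

# Exact permutation distribution of the rank-sum of the first group.
# Midranks doubled to integers; DP over "choose j of the first i values"
# tracks the number of subsets attaining each doubled sum.
rank_sum_exact_p <- function(r, n1) {
  r2 <- as.integer(round(2 * r))
  N <- length(r2)
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  # ways[j+1, s+1]: subsets of size j with doubled-rank sum s
  ways <- matrix(0, nrow = n1 + 1, ncol = smax + 1)
  ways[1, 1] <- 1
  for (v in r2) {
    for (j in min(n1, N):1) {
      shifted <- c(rep(0, v), ways[j, seq_len(smax + 1 - v)])
      ways[j + 1, ] <- ways[j + 1, ] + shifted
    }
  }
  dist <- ways[n1 + 1, ]
  sums <- (seq_along(dist) - 1) / 2
  probs <- dist / sum(dist)
  mu <- n1 * (N + 1) / 2
  obs <- sum(r[seq_len(n1)])
  sum(probs[abs(sums - mu) >= abs(obs - mu) - 1e-9])
}

# Exact distribution of the positive-rank sum of the signed-rank test:
# DP over sign assignments of the doubled midranks.
signed_rank_exact_p <- function(r, w_obs) {
  r2 <- as.integer(round(2 * r))
  smax <- sum(r2)
  ways <- numeric(smax + 1)
  ways[1] <- 1
  for (v in r2) {
    shifted <- c(rep(0, v), ways[seq_len(smax + 1 - v)])
    ways <- ways + shifted
  }
  sums <- (seq_along(ways) - 1) / 2
  probs <- ways / sum(ways)
  mu <- sum(r) / 2
  sum(probs[abs(sums - mu) >= abs(w_obs - mu) - 1e-9])
}

# Exact Kruskal-Wallis upper-tail p by full enumeration of the group
# assignments (used only when the enumeration is small).
kruskal_exact_p <- function(r, nj, h_obs_uncorrected) {
  N <- length(r)
  k <- length(nj)
  hit <- 0
  total <- 0
  recurse <- function(avail, gi, Rsums) {
    if (gi == k) {
      R <- c(Rsums, sum(r[avail]))
      H <- 12 / (N * (N + 1)) * sum(R^2 / nj) - 3 * (N + 1)
      total <<- total + 1
      if (H >= h_obs_uncorrected - 1e-9) hit <<- hit + 1
      return(invisible())
    }
    cb <- utils::combn(length(avail), nj[gi])
    for (i in seq_len(ncol(cb))) {
      idx <- avail[cb[, i]]
      recurse(setdiff(avail, idx), gi + 1, c(Rsums, sum(r[idx])))
    }
  }
  recurse(seq_len(N), 1L, numeric(0))
  hit / total
}

kw_enum_size <- function(nj) {
  N <- sum(nj)
  total <- 1
  rem <- N
  for (n in nj[-length(nj)]) {
    total <- total * choose(rem, n)
    rem <- rem - n
  }
  total
}

MW_EXACT_MAX_N <- 20L     # pooled size up to which the exact MW p is used
WSR_EXACT_MAX_N <- 16L    # nonzero pairs up to which the exact WSR p is used
KW_EXACT_MAX_ENUM <- 1e5  # enumeration budget for the exact KW p

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: %s = %s", x$test, x$statistic_name,
              format(signif(x$statistic, 4))))
  if (!is.na(x$z)) cat(sprintf(", Z = %s", format(signif(x$z, 4))))
  if (!is.na(x$df)) cat(sprintf(", df = %g", x$df))
  if (!is.na(x$p_value)) cat(sprintf(", p = %s", format(signif(x$p_value, 3))))
  cat("\n")
  if (length(x$mean_ranks)) {
    cat("  mean ranks:",
        paste(sprintf("%s = %.2f (n = %d)", names(x$mean_ranks),
                      x$mean_ranks, x$n[names(x$mean_ranks)]),
              collapse = ", "), "\n")
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.stat_result <- function(x, ...) {
  data.frame(test = x$test, statistic_name = x$statistic_name,
             statistic = x$statistic, z = x$z, df = x$df,
             p_value = x$p_value, p_method = x$p_method,
             mean_ranks = paste(sprintf("%s=%.3f", names(x$mean_ranks),
                                        x$mean_ranks), collapse = ";"),
             n = paste(sprintf("%s=%d", names(x$n), x$n), collapse = ";"),
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

tie_term <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

#' Mann-Whitney U test (asymptotic, tie-corrected)
#'
#' Midranks over the pooled sample; reports the smaller U, the signed
#' normal deviate based on the first group, the two-sided p-value (exact
#' permutation p for pooled n <= 20, tie-corrected asymptotic otherwise)
#' and per-group mean ranks.
#'
#' @param group_a,group_b Nonempty numeric vectors.
#' @return A `stat_result`.
#' @export
mann_whitney <- function(group_a, group_b) {
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)
  if (!length(a) || !length(b)) {
    stop_cd26("both groups must be nonempty", class = "cd26_parameter_error")
  }
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  R1 <- sum(r[seq_len(n1)])
  R2 <- sum(r) - R1
  U1 <- R1 - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term(r) / (N * (N - 1)))
  flags <- character(0)
  p_method <- "asymptotic"
  if (sigma2 <= 0) {
    flags <- "degenerate_all_tied"
    z <- NA_real_; p <- NA_real_
  } else {
    z <- (U1 - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    if (N <= MW_EXACT_MAX_N) {
      p <- rank_sum_exact_p(r, n1)
      p_method <- "exact"
    }
  }
  stat_result("Mann-Whitney U", min(U1, U2), "U", z = z, p_value = p,
              mean_ranks = c(a = R1 / n1, b = R2 / n2),
              n = c(a = n1, b = n2), flags = flags, p_method = p_method)
}

#' Kruskal-Wallis test (tie-corrected)
#'
#' H statistic with the standard tie correction, referred to a chi-square
#' distribution on k-1 degrees of freedom (or, for small enumerable
#' layouts, the exact permutation tail); per-group mean ranks reported.
#'
#' @param groups List of two or more nonempty numeric vectors (names kept).
#' @return A `stat_result`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, as.numeric)
  groups <- groups[lengths(groups) > 0]
  k <- length(groups)
  if (k < 2) {
    stop_cd26("need at least 2 nonempty groups",
              class = "cd26_parameter_error")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_len(k))
  }
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  Rj <- tapply(r, factor(g, levels = names(groups)), sum)
  nj <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  C <- 1 - tie_term(r) / (N^3 - N)
  flags <- character(0)
  p_method <- "asymptotic"
  if (C <= 0) {
    flags <- "degenerate_all_tied"
    H <- NA_real_; p <- NA_real_
  } else {
    H_unc <- H
    H <- H / C
    p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
    if (kw_enum_size(nj) <= KW_EXACT_MAX_ENUM) {
      p <- kruskal_exact_p(r, nj, H_unc)
      p_method <- "exact"
    }
  }
  stat_result("Kruskal-Wallis", H, "H (chi-square)", df = k - 1,
              p_value = p,
              mean_ranks = stats::setNames(as.numeric(Rj / nj), names(groups)),
              n = stats::setNames(as.integer(nj), names(groups)),
              flags = flags, p_method = p_method)
}

#' Wilcoxon signed-rank test (asymptotic, tie-corrected)
#'
#' Differences `after - before`; zero differences are dropped, absolute
#' differences midranked, and the positive-rank sum referred to its normal
#' approximation with the tie-correction term (the p-value is exact for up
#' to 16 nonzero pairs). A negative Z means `after` is systematically
#' below `before`.
#'
#' @param before,after Equal-length numeric vectors, pairs aligned by
#'   position.
#' @return A `stat_result` with mean ranks of the negative and positive
#'   differences and the number of ties (dropped zeros).
#' @export
wilcoxon_signed_rank <- function(before, after) {
  b <- as.numeric(before); a <- as.numeric(after)
  if (length(a) != length(b) || !length(a)) {
    stop_cd26("before and after must be nonempty equal-length vectors",
              class = "cd26_parameter_error")
  }
  d <- a - b
  zeros <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(stat_result("Wilcoxon signed-rank", NA_real_, "W", z = NA_real_,
                       p_value = NA_real_,
                       mean_ranks = c(negative = NA_real_,
                                      positive = NA_real_),
                       n = c(negative = 0L, positive = 0L,
                             ties = as.integer(zeros)),
                       flags = "degenerate_all_zero_differences"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - tie_term(r) / 48
  flags <- character(0)
  p_method <- "asymptotic"
  if (sigma2 <= 0) {
    flags <- "degenerate_all_tied"
    z <- NA_real_; p <- NA_real_
  } else {
    z <- (W - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    if (n <= WSR_EXACT_MAX_N) {
      p <- signed_rank_exact_p(r, W)
      p_method <- "exact"
    }
  }
  mr <- c(negative = if (any(d < 0)) mean(r[d < 0]) else NA_real_,
          positive = if (any(d > 0)) mean(r[d > 0]) else NA_real_)
  stat_result("Wilcoxon signed-rank", W, "W", z = z, p_value = p,
              mean_ranks = mr,
              n = c(negative = sum(d < 0), positive = sum(d > 0),
                    ties = as.integer(zeros)),
              flags = flags, p_method = p_method)
}

#' Spearman rank-order correlation
#'
#' rs is the product-moment correlation of midranks; the two-sided p-value
#' uses the t approximation on n-2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return A `stat_result` with `statistic` = rs.
#' @export
spearman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3) {
    stop_cd26("need equal-length vectors with n >= 3",
              class = "cd26_parameter_error")
  }
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(stat_result("Spearman correlation", NA_real_, "rs",
                       n = c(n = n), flags = "degenerate_zero_rank_variance"))
  }
  rs <- stats::cor(rx, ry)
  if (abs(rs) >= 1) {
    p <- 0
  } else {
    tval <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  stat_result("Spearman correlation", rs, "rs", df = n - 2, p_value = p,
              n = c(n = n))
}

#' Median-based summary of a sample
#'
#' Median, min, max and interquartile range, with quartiles by linear
#' interpolation between order statistics (R quantile type 7).
#'
#' @param values Nonempty numeric vector.
#' @return List with `n`, `median`, `min`, `max`, `q1`, `q3`, `iqr`.
#' @export
summarize_values <- function(values) {
  x <- as.numeric(values)
  x <- x[!is.na(x)]
  if (!length(x)) {
    stop_cd26("cannot summarize an empty sample",
              class = "cd26_parameter_error")
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(n = length(x), median = q[2], min = min(x), max = max(x),
       q1 = q[1], q3 = q[3], iqr = q[3] - q[1])
}
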