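# Independent oracles, deliberately implemented by routes different from the
# package code they check.

# Poisson-binomial pmf by brute-force enumeration of all 2^n outcomes.
enum_pb_pmf <- function(probs) {
  n <- length(probs)
  pmf <- numeric(n + 1)
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask)[1:n])
    pr <- prod(ifelse(bits == 1, probs, 1 - probs))
    k <- sum(bits)
    pmf[k + 1] <- pmf[k + 1] + pr
  }
  pmf
}

enum_pb_tail <- function(probs, k_obs, inclusive = TRUE) {
  pmf <- enum_pb_pmf(probs)
  k_min <- if (inclusive) k_obs else k_obs + 1
  if (k_min > length(probs)) return(0)
  sum(pmf[seq.int(k_min + 1, length(pmf))])
}

# High-precision log-space recomputation of the upper tail, written as a
# column-wise recurrence over counts (different loop structure from the
# package's row-wise log DP).
logspace_pb_tail <- function(probs, k_obs) {
  n <- length(probs)
  lse2 <- function(x, y) {
    if (x == -Inf) return(y)
    if (y == -Inf) return(x)
    m <- max(x, y)
    m + log1p(exp(min(x, y) - m))
  }
  lf <- c(0, rep(-Inf, n))
  lp <- log(probs)
  lq <- log1p(-probs)
  for (j in seq_len(n)) {
    for (k in rev(seq_len(min(j, n)) + 1L)) {   # update high counts first
      lf[k] <- lse2(lf[k] + lq[j], lf[k - 1] + lp[j])
    }
    lf[1] <- lf[1] + lq[j]
  }
  if (k_obs > n) return(0)
  terms <- lf[seq.int(k_obs + 1, n + 1)]
  terms <- terms[is.finite(terms)]
  if (!length(terms)) return(0)
  m <- max(terms)
  exp(m + log(sum(exp(terms - m))))
}

# Exact 2x2 test by direct enumeration of tables with fixed margins, using
# log-binomial coefficients only (no d/phyper).
enum_fisher_2x2 <- function(a, b, c, d, sided = "two") {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p <- exp(logp)
  obs <- p[support == a]
  if (sided == "greater") return(sum(p[support >= a]))
  if (sided == "less") return(sum(p[support <= a]))
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# Hand-rolled two-group log-rank statistic (observed-minus-expected form).
hand_logrank <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  O <- E <- V <- 0
  for (t in times) {
    n1 <- sum(t1 >= t); n2 <- sum(t2 >= t); n <- n1 + n2
    d1 <- sum(t1 == t & e1 == 1); d2 <- sum(t2 == t & e2 == 1)
    d <- d1 + d2
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
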