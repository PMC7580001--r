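#' Exact Poisson-binomial probability mass function
#'
#' Distribution of the number of successes among independent Bernoulli trials
#' with unequal success probabilities, computed exactly by the prefix
#' convolution dynamic programme
#' \eqn{f_j(k) = f_{j-1}(k)(1-p_j) + f_{j-1}(k-1)p_j}.
#'
#' This is the null distribution of the number of mutations landing in the
#' domain-encoding regions of a gene family when each mutation independently
#' hits the domain with probability (domain span)/(protein length).
#'
#' @param probs Numeric vector of success probabilities, each in \[0, 1\].
#' @return Numeric vector of length `length(probs) + 1`: `P(N = k)` for
#'   `k = 0, ..., n`. Sums to 1 within 1e-12.
#' @examples
#' poisson_binomial_pmf(c(0.1, 0.2, 0.3))
#' @export
poisson_binomial_pmf <- function(probs) {
  probs <- check_probs(probs)
  n <- length(probs)
  f <- c(1, numeric(n))
  for (j in seq_len(n)) {
    p <- probs[j]
    # full-vector update keeps the recurrence branch-free; O(n^2) total
    f <- f * (1 - p) + c(0, f[-(n + 1)]) * p
  }
  f
}

#' Poisson-binomial pmf on the log scale
#'
#' Same recurrence as [poisson_binomial_pmf()] carried out entirely in log
#' space with log-sum-exp accumulation, so probability masses far below the
#' double-precision underflow threshold remain representable. Used
#' automatically by [poisson_binomial_tail()] when the plain-double tail
#' underflows.
#'
#' @inheritParams poisson_binomial_pmf
#' @return Numeric vector of `log P(N = k)` for `k = 0, ..., n` (`-Inf` for
#'   impossible counts).
#' @export
poisson_binomial_log_pmf <- function(probs) {
  probs <- check_probs(probs)
  n <- length(probs)
  lf <- c(0, rep(-Inf, n))
  for (j in seq_len(n)) {
    lp <- log(probs[j])
    lq <- log1p(-probs[j])
    a <- lf + lq
    b <- c(-Inf, lf[-(n + 1)]) + lp
    hi <- pmax(a, b)
    lf <- ifelse(is.infinite(hi) & hi < 0, -Inf,
                 hi + log1p(exp(pmin(a, b) - hi)))
  }
  lf
}

#' Exact Poisson-binomial tail p-value
#'
#' Upper-tail probability of the Poisson-binomial count. `inclusive = TRUE`
#' (the default) returns the standard exact one-sided p-value
#' \eqn{P(N \ge k_{obs})}; `inclusive = FALSE` returns the strict event
#' \eqn{P(N > k_{obs})}.
#'
#' Computed from the dynamic-programming pmf in plain double precision; when
#' the summed tail underflows (below ~1e-280) the log-space recurrence of
#' [poisson_binomial_log_pmf()] takes over, so tails down to the smallest
#' representable double are returned accurately.
#'
#' @inheritParams poisson_binomial_pmf
#' @param k_obs Observed count, an integer in `0:length(probs)`.
#' @param inclusive Logical; if `TRUE` return `P(N >= k_obs)`, else
#'   `P(N > k_obs)`.
#' @return A single p-value in \[0, 1\].
#' @examples
#' poisson_binomial_tail(c(0.1, 0.2, 0.3), 2)                    # 0.098
#' poisson_binomial_tail(c(0.1, 0.2, 0.3), 2, inclusive = FALSE) # 0.006
#' @export
poisson_binomial_tail <- function(probs, k_obs, inclusive = TRUE) {
  probs <- check_probs(probs)
  n <- length(probs)
  if (!is.numeric(k_obs) || length(k_obs) != 1L || is.na(k_obs) ||
      k_obs != trunc(k_obs)) {
    stop("`k_obs` must be a single integer.", call. = FALSE)
  }
  if (k_obs < 0 || k_obs > n) {
    stop("`k_obs` must lie in 0..", n, " (got ", k_obs, ").", call. = FALSE)
  }
  k_min <- if (inclusive) k_obs else k_obs + 1
  if (k_min > n) return(0)
  if (k_min <= 0) return(1)
  f <- poisson_binomial_pmf(probs)
  idx <- seq.int(k_min + 1L, n + 1L)
  # accumulate from the extreme tail inwards: smallest terms first
  tail_p <- sum(f[rev(idx)])
  if (tail_p < 1e-280) {
    lf <- poisson_binomial_log_pmf(probs)[idx]
    lf <- lf[is.finite(lf)]
    if (length(lf) == 0L) return(0)
    m <- max(lf)
    tail_p <- exp(m + log(sum(exp(lf - m))))
  }
  min(tail_p, 1)
}

check_probs <- function(probs) {
  if (!is.numeric(probs) || length(probs) == 0L) {
    stop("`probs` must be a non-empty numeric vector.", call. = FALSE)
  }
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    stop("All probabilities must lie in [0, 1].", call. = FALSE)
  }
  as.numeric(probs)
}
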