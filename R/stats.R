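#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval for a binomial proportion: the lower bound is the success
#' probability at which observing k or more successes has probability
#' alpha/2 (0 when k = 0) and the upper bound the probability at which
#' observing k or fewer has probability alpha/2 (1 when k = n), obtained via
#' the beta-quantile form of the binomial tail.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param alpha Total tail probability (default 0.05 for a 95% interval).
#' @return Numeric vector `c(low, high)`.
#' @export
clopper_pearson_ci <- function(k, n, alpha = 0.05) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n))
    stop("k and n must be scalars")
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n with n >= 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  low <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  high <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  c(low = low, high = high)
}

# U statistic from midranks: number of (a, b) pairs with a > b, ties counted
# one half. Computed for sample a against sample b.
mw_u_stat <- function(a, b) {
  r <- rank(c(a, b))  # midranks
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a difference between two independent samples. The U
#' statistic uses midranks, so ties contribute one half. Exact two-sided
#' p-values are computed by full enumeration of all assignments of the
#' pooled observations to the two groups (valid with ties); for larger
#' samples a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param sample_a,sample_b Numeric vectors, both non-empty.
#' @param mode `"auto"` (exact when the combined sample size allows
#'   enumeration, default), `"exact"`, or `"approximate"`.
#' @param exact_limit Largest combined sample size for which enumeration is
#'   attempted (default 14).
#' @return A list with `U` (for `sample_a`), `p` (two-sided), and `method`.
#' @export
mann_whitney <- function(sample_a, sample_b,
                         mode = c("auto", "exact", "approximate"),
                         exact_limit = 14) {
  mode <- match.arg(mode)
  if (!length(sample_a) || !length(sample_b)) stop("both samples must be non-empty")
  na <- length(sample_a); nb <- length(sample_b); N <- na + nb
  u <- mw_u_stat(sample_a, sample_b)
  if (mode == "auto") mode <- if (N <= exact_limit) "exact" else "approximate"
  if (mode == "exact") {
    if (N > exact_limit)
      stop(sprintf("combined n = %d exceeds the enumeration bound %d; use mode = 'approximate'",
                   N, exact_limit))
    r <- rank(c(sample_a, sample_b))
    idx <- combn(N, na)
    mu <- na * nb / 2
    us <- apply(idx, 2, function(ii) sum(r[ii])) - na * (na + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
  } else {
    mu <- na * nb / 2
    ties <- table(c(sample_a, sample_b))
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = u, p = 1, method = "approximate"))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- min(1, 2 * pnorm(z, lower.tail = FALSE))
  }
  list(U = u, p = p, method = mode)
}
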