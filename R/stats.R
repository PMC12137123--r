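#' Kruskal-Wallis rank test
#'
#' Non-parametric omnibus comparison of k independent groups. Uses midranks,
#' the tie-corrected H statistic
#' \deqn{H = \frac{12}{N(N+1)} \sum_i n_i (\bar r_i - (N+1)/2)^2 \Big/
#'       \left(1 - \sum_t (t^3 - t)/(N^3 - N)\right)}
#' and a chi-square reference distribution with k - 1 degrees of freedom.
#' When every observation is identical the statistic is 0 and p = 1.
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the response and the grouping
#'   variable.
#' @return One-row tibble: `statistic` (H), `df`, `p.value`, `method`.
#' @export
#' @examples
#' kruskal_wallis(data.frame(v = c(1, 2, 3, 4), g = c("a", "a", "b", "b")),
#'                "v", "g")
kruskal_wallis <- function(data, value = "value", group = "group") {
  df <- as.data.frame(data)
  x <- df[[value]]
  g <- as.factor(df[[group]])
  if (any(!is.finite(x))) abort("values must be finite")
  k <- nlevels(g)
  N <- length(x)
  if (k < 2) abort("need at least 2 groups")
  if (N < 3) abort("need at least 3 observations in total")
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (correction <= 0) {
    H <- 0
    p <- 1
  } else {
    H <- H / correction
    p <- pchisq(H, df = k - 1, lower.tail = FALSE)
  }
  tibble(statistic = H, df = k - 1, p.value = p,
         method = "Kruskal-Wallis rank sum test (tie-corrected)")
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test for two independent samples, with midranks for
#' ties. When the pooled sample is small (`n_a + n_b <= exact_threshold`) the
#' p-value is exact: every assignment of the pooled midranks to the first
#' sample is enumerated and the p-value is the probability of a rank sum at
#' least as far from its null mean as the one observed. Otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact_threshold Largest pooled size for which the exact enumeration
#'   is used (default 12).
#' @return One-row tibble: `statistic` (rank sum W of `a`), `p.value`,
#'   `method`.
#' @export
#' @examples
#' rank_sum(c(1, 2), c(3, 4)) # exact two-sided p = 1/3
rank_sum <- function(a, b, exact_threshold = 12) {
  if (length(a) < 1 || length(b) < 1) abort("both samples must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b))) abort("values must be finite")
  na <- length(a)
  nb <- length(b)
  N <- na + nb
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  mu <- na * (N + 1) / 2
  if (N <= exact_threshold) {
    combos <- utils::combn(N, na)
    Ws <- colSums(matrix(r[combos], nrow = na))
    p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
    method <- "Wilcoxon rank-sum test (exact enumeration, two-sided)"
  } else {
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
    method <- "Wilcoxon rank-sum test (normal approximation, two-sided)"
  }
  tibble(statistic = W, p.value = p, method = method)
}

#' Holm step-down multiple-testing adjustment
#'
#' Sorts the m raw p-values ascending, multiplies the j-th smallest by
#' (m - j + 1), enforces monotonicity by running maxima, caps at 1, and
#' restores the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
holm_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must be in [0, 1]")
  }
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}
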