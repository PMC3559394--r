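#' Paired Wilcoxon signed-rank test with exact small-sample p
#'
#' Signed-rank test on paired per-focal values. Zero differences are dropped
#' before ranking (the standard signed-rank convention); ties in the absolute
#' differences receive average ranks. For `n <= exact_max` informative pairs
#' the two-sided p-value is exact, computed from the full enumeration of the
#' `2^n` equiprobable sign patterns of the observed (possibly tied) ranks;
#' beyond that the tie-corrected normal approximation is used. The reported
#' `z` is always the tie-corrected normal deviate
#' \eqn{(W^+ - \mu)/\sigma}, positive when `a` tends to exceed `b`.
#'
#' @param a,b equal-length numeric vectors, paired by position (one entry
#'   per focal individual). Pairs with `NA` in either member are dropped.
#' @param exact_max largest `n` for which the exact distribution is used.
#' @return list: `w` (sum of positive ranks), `z`, `p` (two-tailed),
#'   `n_effective`, `method`, `defined` (`FALSE` with `NA` statistics when
#'   fewer than 2 informative pairs remain).
#' @export
wilcoxon_paired <- function(a, b, exact_max = 12L) {
  keep <- !(is.na(a) | is.na(b))
  d <- a[keep] - b[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n < 2) {
    return(list(w = NA_real_, z = NA_real_, p = NA_real_,
                n_effective = n, method = "undefined", defined = FALSE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) (w - mu) / sqrt(sigma2) else 0
  if (n <= exact_max) {
    dist <- signed_rank_distribution(r)
    # the null distribution is symmetric about mu (sign flips map W to 2mu-W)
    p <- sum(dist$prob[abs(dist$w - mu) >= abs(w - mu) - 1e-9])
    method <- "exact_enumeration"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_tie_corrected"
  }
  list(w = w, z = z, p = min(p, 1), n_effective = n, method = method,
       defined = TRUE)
}

#' Exact null distribution of the positive-rank sum
#'
#' Distribution of \eqn{W^+} over all `2^n` sign patterns of the given rank
#' vector (average ranks allowed). Used for exact p-values; exported because
#' calibration tests reuse it.
#'
#' @param ranks numeric rank vector of the absolute differences.
#' @return data frame `w`, `prob`.
#' @export
signed_rank_distribution <- function(ranks) {
  n <- length(ranks)
  assert_that(n <= 20, "exact enumeration limited to n <= 20",
              class = "pcmc_contract_error")
  # convolve one rank at a time over the lattice of attainable sums
  vals <- c(0)
  prob <- c(1)
  for (rk in ranks) {
    v2 <- c(vals, vals + rk)
    p2 <- c(prob, prob) / 2
    agg <- tapply(p2, round(v2, 9), sum)
    vals <- as.numeric(names(agg))
    prob <- as.numeric(agg)
  }
  data.frame(w = vals, prob = prob)
}

#' Bonferroni-corrected significance threshold
#'
#' `nominal / k`, truncated (not rounded) to `digits` decimals -- three
#' comparisons at nominal 0.05 give 0.016.
#'
#' @param nominal nominal alpha.
#' @param k number of comparisons.
#' @param digits decimals kept by truncation.
#' @return corrected alpha.
#' @export
bonferroni_alpha <- function(nominal = 0.05, k = 3L, digits = 3L) {
  floor(nominal / k * 10^digits) / 10^digits
}
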