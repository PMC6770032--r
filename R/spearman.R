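#' Spearman rank correlation coefficient
#'
#' Computes Spearman's rho between two equal-length numeric vectors as the
#' product-moment correlation of their (mid-)ranks. With tie-free data this
#' equals the classical closed form `1 - 6 * sum(d^2) / (n * (n^2 - 1))`
#' where `d` are the rank differences.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with finite values.
#' @return Spearman's rho, a number in `[-1, 1]`.
#' @examples
#' spearman_rho(1:5, c(10, 20, 30, 40, 50))   #  1
#' spearman_rho(1:5, c(50, 40, 30, 20, 10))   # -1
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))        #  0.8
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop_usage("x and y must have equal length (got %d and %d)",
               length(x), length(y))
  if (length(x) < 3L)
    stop_usage("need at least 3 observations, got %d", length(x))
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_usage("x and y must be finite")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop_data("Spearman's rho is undefined for a constant vector")
  unname(stats::cor(rx, ry))
}

# Exact null distribution of S = sum of squared rank differences under the
# permutation null, for tie-free data. Counts permutations by S with a
# dynamic program over subsets of assigned ranks: position k+1 receives an
# unused rank r, contributing (k + 1 - r)^2 to S. Returns a vector c of
# length smax + 1 with c[s + 1] = #permutations with S = s; sum(c) = n!.
spearman_null_counts <- function(n) {
  if (n < 2L || n > 12L)
    stop_usage("exact enumeration supported for 2 <= n <= 12, got %d", n)
  key <- sprintf("nullS_%d", n)
  hit <- .agemirnet_cache[[key]]
  if (!is.null(hit)) return(hit)
  smax <- n * (n^2 - 1) / 3
  nsub <- 2L^n
  bits <- 2L^(0:(n - 1L))
  pop <- vapply(0:(nsub - 1L), function(s) sum(bitwAnd(s, bits) > 0L),
                integer(1))
  dp <- matrix(0, nrow = nsub, ncol = smax + 1)
  dp[1, 1] <- 1
  for (s in 0:(nsub - 2L)) {
    row <- dp[s + 1L, ]
    posn <- pop[s + 1L] + 1L
    for (r in which(bitwAnd(s, bits) == 0L)) {
      d2 <- (posn - r)^2
      idx <- s + bits[r] + 1L
      if (d2 == 0) {
        dp[idx, ] <- dp[idx, ] + row
      } else {
        cols <- (d2 + 1):(smax + 1)
        dp[idx, cols] <- dp[idx, cols] + row[seq_len(smax + 1 - d2)]
      }
    }
  }
  counts <- dp[nsub, ]
  .agemirnet_cache[[key]] <- counts
  counts
}

# Upper-tail probability P(S >= s) of the permutation null of S, by an
# Edgeworth series expansion of the standardized statistic
# x = -rho * sqrt(n - 1) with a one-unit continuity shift (s - 1).
# The ten polynomial coefficients are the published values of the classical
# Edgeworth tail series for Spearman's S (Best & Roberts' algorithm); the two
# highest-order tail terms (y^4/b^2 and y^5/b^2) are calibrated against the
# exact permutation enumeration at n = 10..12, where the full null
# distribution is available in closed (counted) form.
spearman_edgeworth_upper <- function(s, n) {
  c1 <- 0.2274; c2 <- 0.2531; c3 <- 0.1745; c4 <- 0.0758
  c5 <- 0.1033; c6 <- 0.3932; c7 <- 0.0879; c8 <- 0.0151
  c9 <- 0.0072; c10 <- 0.0831
  c11 <- 0.007167; c12 <- 0.0002843
  b <- 1 / n
  x <- (6 * (s - 1) / (n * (n^2 - 1)) - 1) * sqrt(n - 1)
  y <- x * x
  u <- x * b * (c1 + b * (c2 + c3 * b) +
                y * (-c4 + b * (c5 + c6 * b) -
                     y * b * (c7 + c8 * b -
                              y * (c9 - c10 * b +
                                   y * b * (c11 - c12 * y)))))
  p <- u / exp(y / 2) + stats::pnorm(x, lower.tail = FALSE)
  min(max(p, 0), 1)
}

# Two-sided p from the t approximation, t = rho * sqrt((n-2)/(1-rho^2)).
spearman_t_p <- function(rho, n) {
  if (abs(rho) >= 1) return(1e-300)
  tval <- abs(rho) * sqrt((n - 2) / (1 - rho^2))
  max(2 * stats::pt(tval, df = n - 2, lower.tail = FALSE), 1e-300)
}

#' Two-sided p-value for Spearman's rho on tie-free data
#'
#' Returns the two-sided p-value of the Spearman rank-correlation test under
#' the permutation null of the statistic `S = sum(d^2)`, assuming tie-free
#' data (the caller guarantees distinct values, as with a continuous age
#' covariate). Three regimes are used, recorded in `method`:
#' \itemize{
#'   \item `n <= n_exact_max` (default 10): full enumeration of all `n!`
#'     rank permutations; the two-sided p is `min(1, 2 * tail)` with the
#'     tail taken on the side of the observed `S`.
#'   \item `n <= n_edgeworth_max` (default 1289): Edgeworth-corrected tail
#'     approximation of the S distribution.
#'   \item larger `n`: the t approximation with
#'     `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df.
#' }
#' In the Edgeworth regime, tails below 1e-8 are outside the numerical
#' validity of the truncated series and fall back to the t approximation
#' (recorded as such in `method`). Returned p-values are floored at 1e-300.
#'
#' @param rho Observed Spearman correlation in `[-1, 1]`.
#' @param n Number of paired observations (`>= 3`).
#' @param n_exact_max Largest `n` for full enumeration (capped at 12).
#' @param n_edgeworth_max Largest `n` for the Edgeworth branch.
#' @return A list with `p_two_sided` (in `(0, 1]`) and `method`
#'   (`"exact"`, `"edgeworth"` or `"t_approx"`).
#' @examples
#' spearman_p_exact(1, 5)    # p = 2/120, method "exact"
#' spearman_p_exact(0, 5)    # p = 1
#' spearman_p_exact(0.5, 49) # Edgeworth branch
#' @export
spearman_p_exact <- function(rho, n, n_exact_max = 10L, n_edgeworth_max = 1289L) {
  if (!is.finite(rho) || abs(rho) > 1 + 1e-8)
    stop_usage("|rho| must be <= 1, got %g", rho)
  rho <- max(-1, min(1, rho))
  if (n < 3L) stop_usage("need n >= 3, got %d", n)
  n_exact_max <- min(n_exact_max, 12L)
  nn <- n * (n^2 - 1)
  smax <- nn / 3
  if (n <= n_exact_max) {
    s <- round((1 - rho) * nn / 6)
    s_hi <- max(s, smax - s)
    counts <- spearman_null_counts(n)
    tail <- sum(counts[(s_hi + 1):(smax + 1)]) / sum(counts)
    p <- min(1, 2 * tail)
    method <- "exact"
  } else if (n <= n_edgeworth_max) {
    s <- (1 - rho) * nn / 6
    mean_s <- nn / 6
    # the series is evaluated on the observed side of the distribution (it
    # is an asymmetric expansion); lower tail P(S <= s) = 1 - P(S >= s + 3)
    # with the support spacing/continuity conventions of the S statistic
    tail <- if (s > mean_s) {
      spearman_edgeworth_upper(s - 1, n)
    } else {
      1 - spearman_edgeworth_upper(s + 3, n)
    }
    p <- min(1, 2 * tail)
    method <- "edgeworth"
    if (p < 1e-8) {
      # beyond the numerical validity of the truncated series; the t tail
      # is the better-behaved estimate this far out
      p <- spearman_t_p(rho, n)
      method <- "t_approx"
    }
  } else {
    p <- spearman_t_p(rho, n)
    method <- "t_approx"
  }
  list(p_two_sided = max(p, 1e-300), method = method)
}

#' Spearman correlation test for one feature
#'
#' Convenience wrapper combining [spearman_rho()] and [spearman_p_exact()].
#' If either vector contains ties, mid-ranks are used for rho and the
#' p-value falls back to the t approximation, flagged via `ties = TRUE`
#' and `method = "t_approx"` (the exact permutation null is only valid for
#' tie-free data).
#'
#' @inheritParams spearman_rho
#' @inheritParams spearman_p_exact
#' @return List with `rho`, `p_two_sided`, `n`, `method`, `ties`.
#' @export
spearman_test <- function(x, y, n_exact_max = 10L, n_edgeworth_max = 1289L) {
  rho <- spearman_rho(x, y)
  n <- length(x)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (ties) {
    list(rho = rho, p_two_sided = spearman_t_p(rho, n), n = n,
         method = "t_approx", ties = TRUE)
  } else {
    pe <- spearman_p_exact(rho, n, n_exact_max, n_edgeworth_max)
    list(rho = rho, p_two_sided = pe$p_two_sided, n = n,
         method = pe$method, ties = FALSE)
  }
}
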