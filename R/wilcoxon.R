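#' Exact Wilcoxon matched-pairs signed-rank test
#'
#' Paired test on differences `d = a - b`. Zero differences are dropped
#' (Wilcoxon convention), `|d|` is ranked with midranks for ties, and the
#' statistic `W` is the sum of the ranks of the positive differences. The
#' two-sided p-value is exact for up to 25 non-zero pairs: under the null
#' every one of the `2^m` sign assignments is equally likely, and the
#' p-value sums the probabilities of all assignments whose `W` deviates from
#' its null mean `m(m+1)/4` at least as much as the observed one. The exact
#' null distribution is obtained by convolution over the (doubled, hence
#' integer) midranks, which enumerates the same `2^m` assignment
#' distribution without materialising it. Beyond 25 pairs a normal
#' approximation with tie-corrected variance and continuity correction is
#' used and flagged in `method`.
#'
#' @param a,b Numeric vectors of paired observations, or a two-column
#'   data frame/matrix in `a` with `b` missing.
#' @param exact_limit Largest number of non-zero pairs for which the exact
#'   distribution is computed (default 25).
#' @returns A one-row tibble: `W`, `p_value`, `m` (non-zero pairs),
#'   `method` (`"exact"` or `"normal"`), `degenerate` (`TRUE` when all
#'   differences are zero, reported as `W = 0`, `p = 1`).
#' @examples
#' wilcoxon_signed_rank_exact(c(3, 5, 7), c(1, 2, 3)) # W = 6, p = 0.25
#' @export
wilcoxon_signed_rank_exact <- function(a, b = NULL, exact_limit = 25) {
  if (is.null(b)) {
    a <- as.data.frame(a)
    stopifnot(ncol(a) == 2)
    b <- a[[2]]
    a <- a[[1]]
  }
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  keep <- !(is.na(a) | is.na(b))
  d <- a[keep] - b[keep]
  if (length(d) == 0) abort("Need at least one pair.")
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    return(tibble(W = 0, p_value = 1, m = 0L, method = "exact",
                  degenerate = TRUE))
  }
  r <- rank(abs(d)) # midranks for ties
  W <- sum(r[d > 0])
  mu <- m * (m + 1) / 4
  if (m <= exact_limit) {
    # Null distribution of 2*W over the 2^m equiprobable sign assignments,
    # by convolving the generating polynomial of each doubled rank.
    r2 <- as.integer(round(2 * r))
    total2 <- sum(r2)
    f <- rep(0, total2 + 1) # f[k+1] = #assignments with 2W = k
    f[1] <- 1
    for (ri in r2) {
      g <- f
      g[(ri + 1):(total2 + 1)] <- g[(ri + 1):(total2 + 1)] + f[1:(total2 + 1 - ri)]
      f <- g
    }
    dev <- abs((0:total2) / 2 - mu)
    obs_dev <- abs(W - mu)
    # tolerance guards float comparison of half-integer deviations
    p <- sum(f[dev >= obs_dev - 1e-9]) / 2^m
    method <- "exact"
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    z <- (abs(W - mu) - 0.5) / sigma
    z <- max(z, 0)
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal"
  }
  tibble(W = W, p_value = p, m = as.integer(m), method = method,
         degenerate = FALSE)
}
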