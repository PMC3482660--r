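#' Rank a gene universe by abundance
#'
#' Stable ranking for the sliding-window scan: order by copies (descending by
#' default), ties broken by feature id so the ranking is reproducible.
#'
#' @param expression an `expression_table` (`id`, `copies`, `detected`).
#' @param decreasing rank from most to least abundant (default).
#' @return character vector of ids, a permutation of the detected universe.
#' @export
rank_genes <- function(expression, decreasing = TRUE) {
  expr <- expression[expression$detected & !is.na(expression$copies), ]
  ord <- order(if (decreasing) -expr$copies else expr$copies, expr$id)
  expr$id[ord]
}

#' Sliding-window Fisher enrichment along a ranked gene list
#'
#' Slides a window of `window` genes along the abundance-ranked universe and
#' tests each window for over-representation of a functional category with a
#' one-sided Fisher exact test (the hypergeometric tail of the window/category
#' overlap against the rest of the universe). P values are corrected across
#' all windows of the category with the Benjamini-Hochberg FDR method.
#'
#' @param ranked character vector of ranked gene ids ([rank_genes()]).
#' @param category character vector of category member ids (subset of
#'   `ranked`, nonempty).
#' @param window window size in genes.
#' @param step stride between window starts (1 = fully sliding).
#' @param alternative `"greater"` for over-representation (default) or
#'   `"two.sided"`.
#' @return tibble (`start`, `window`, `k`, `p`, `q`), one row per window.
#' @export
sliding_window_test <- function(ranked, category, window = 200L, step = 1L,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (anyDuplicated(ranked)) stop("ranked list contains duplicates", call. = FALSE)
  if (length(category) == 0L) stop("empty category", call. = FALSE)
  if (!all(category %in% ranked)) {
    stop("category must be a subset of the ranked universe", call. = FALSE)
  }
  N <- length(ranked)
  if (window > N) stop("window larger than universe", call. = FALSE)
  K <- length(unique(category))
  member <- as.integer(ranked %in% category)
  cs <- c(0L, cumsum(member))
  starts <- seq.int(1L, N - window + 1L, by = step)
  k <- cs[starts + window] - cs[starts]
  p <- if (alternative == "greater") {
    phyper(k - 1L, K, N - K, window, lower.tail = FALSE)
  } else {
    vapply(k, function(ki) hyper_two_sided(ki, K, N, window), numeric(1))
  }
  tibble::tibble(start = starts, window = window, k = k,
                 p = pmin(p, 1), q = adjust_fdr(pmin(p, 1)))
}

## minimum-likelihood two-sided hypergeometric p (fisher.test convention)
hyper_two_sided <- function(k, K, N, n) {
  support <- max(0L, n - (N - K)):min(n, K)
  d <- dhyper(support, K, N - K, n)
  sum(d[d <= d[support == k] * (1 + 1e-7)])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate correction; monotone, with `q >= p` and
#' `q <= 1`.
#'
#' @param pvalues p values in `[0, 1]`.
#' @return adjusted q values.
#' @export
adjust_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' One-sided exact binomial association test
#'
#' Tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`: does a property
#' occur among `n` trials more often than the background fraction `p0`
#' (e.g. are genes with an abundant antisense RNA repressed in zone 1 more
#' often than sense genes at large)?
#'
#' @param k_successes observed successes (0 <= k <= n).
#' @param n_trials number of trials.
#' @param p0 background success probability, in (0, 1).
#' @return the one-sided p value.
#' @export
binomial_association <- function(k_successes, n_trials, p0) {
  if (n_trials < 1 || k_successes < 0 || k_successes > n_trials) {
    stop("need 0 <= k <= n with n >= 1", call. = FALSE)
  }
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)", call. = FALSE)
  binom.test(k_successes, n_trials, p = p0, alternative = "greater")$p.value
}
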