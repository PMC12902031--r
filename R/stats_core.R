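# Exact and classical statistics used across the pipeline.

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment of a p-value vector. `NA` entries (untestable events)
#' are excluded from the number of tests `m` and returned as `NA`, so FDR is
#' computed over testable events only.
#'
#' @param p Numeric vector of p-values in `[0, 1]`; `NA` allowed.
#' @return Numeric vector of adjusted p-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) abort("`p` must be non-empty.")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    abort(sprintf("p-values outside [0, 1] at positions: %s",
                  paste(which(bad), collapse = ", ")))
  }
  p.adjust(p, method = "BH")
}

# Mann-Whitney U from mid-ranks of the pooled sample for the labelling in
# which `idx` marks the positions of sample x
u_from_ranks <- function(r, idx, n) {
  sum(r[idx]) - n * (n + 1) / 2
}

#' Exact two-sided Mann-Whitney test by full enumeration
#'
#' Computes the exact two-sided p-value of the Mann-Whitney U statistic by
#' enumerating all `choose(n + m, n)` assignments of the pooled observations
#' to the two groups. Ties are handled with mid-ranks; no normal
#' approximation or continuity correction is involved, which keeps the test
#' exact for the very small group sizes typical of cell-proliferation
#' assays (e.g. n = m = 4, where the smallest achievable two-sided p is
#' 2/70).
#'
#' @param x,y Numeric vectors (group samples); combined length at most 20.
#' @return A list with elements `statistic` (U for `x`), `p_value`
#'   (two-sided exact) and `n_arrangements`.
#' @examples
#' exact_mannwhitney(c(1, 2, 3, 4), c(5, 6, 7, 8))$p_value  # 2/70
#' @export
exact_mannwhitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    abort("Both samples must be non-empty.")
  }
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) abort("Samples must not contain NA.")
  n <- length(x); m <- length(y)
  if (n + m > 20L) {
    abort("Full enumeration supports combined sample size <= 20.")
  }
  pooled <- c(x, y)
  r <- rank(pooled)                    # mid-ranks under ties
  eu <- n * m / 2                      # E[U] under exchangeability
  u_obs <- u_from_ranks(r, seq_len(n), n)
  dev_obs <- abs(u_obs - eu)
  idx_all <- combn(n + m, n)
  devs <- abs(apply(idx_all, 2L, function(idx) u_from_ranks(r, idx, n)) - eu)
  tol <- 1e-9
  list(
    statistic = u_obs,
    p_value = mean(devs >= dev_obs - tol),
    n_arrangements = ncol(idx_all)
  )
}

#' Two-proportion chi-square test with continuity correction
#'
#' Compares `k1/n1` with `k2/n2` via the 2x2 chi-square test with Yates
#' continuity correction (df = 1), matching `stats::prop.test()` defaults.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return A list with `statistic`, `p_value`, `estimate` (the two
#'   proportions).
#' @examples
#' two_proportion_test(20, 100, 40, 100)
#' @export
two_proportion_test <- function(k1, n1, k2, n2) {
  for (v in list(n1 = n1, n2 = n2)) {
    if (!is.numeric(v) || v <= 0) abort("Group totals must be positive.")
  }
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    abort("Counts must satisfy 0 <= k <= n.")
  }
  ht <- suppressWarnings(
    prop.test(c(k1, k2), c(n1, n2), correct = TRUE)
  )
  list(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    estimate = unname(ht$estimate)
  )
}
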