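## Segregation and phenotype statistics: exact combinatorial tests built as
## explicit tail/enumeration sums (two-sided p-values use the
## small-p-values / minimum-likelihood convention of common statistical
## software), plus the phenotype tally utilities.

# Relative tolerance when collecting outcomes no more probable than the
# observed one (guards against floating-point ties).
.rel_err <- 1 + 1e-7

#' Tally phenotype classes
#'
#' Counts classifications (e.g. `wild_type` / `mosaic` / `severe`, or any
#' labels) and reports per-class fractions and percentages. Percentages are
#' returned unrounded; print them with [format_pct()] at the precision the
#' report requires (e.g. one decimal for a segregation ratio, integers for
#' editing-efficiency summaries).
#'
#' @param classifications Vector of class labels.
#' @return A tibble with columns `class`, `count`, `fraction`, `percent`,
#'   and attribute `total`.
#' @export
#' @examples
#' tally_phenotypes(rep(c("wild_type", "mosaic", "severe"), c(3, 14, 15)))
tally_phenotypes <- function(classifications) {
  total <- length(classifications)
  tab <- table(as.character(classifications))
  out <- tibble(
    class = names(tab),
    count = as.integer(tab),
    fraction = if (total == 0) numeric(0) else as.integer(tab) / total
  )
  out$percent <- 100 * out$fraction
  attr(out, "total") <- total
  out
}

#' Exact binomial test
#'
#' Exact tail sums under Binomial(`n`, `p0`). The two-sided p-value is the
#' sum of the probabilities of all outcomes no more probable than the
#' observed one (small-p-values method).
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return A one-row tibble: `statistic` (k), `estimate` (k/n), `p_value`,
#'   `sidedness`, `method`.
#' @export
#' @examples
#' binomial_exact_test(47, 47, 0.5) # all 47 genotyped mutants male
binomial_exact_test <- function(k, n, p0 = 0.5,
                                alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      k < 0 || n < 1 || k > n || k != round(k) || n != round(n)) {
    abort("`k` and `n` must be integers with 0 <= k <= n and n >= 1.")
  }
  if (p0 <= 0 || p0 >= 1) abort("`p0` must be strictly between 0 and 1.")
  d <- dbinom(0:n, n, p0)
  p <- switch(alternative,
    two.sided = sum(d[d <= d[k + 1] * .rel_err]),
    greater = sum(d[(k:n) + 1]),
    less = sum(d[0:k + 1])
  )
  tibble(
    statistic = as.integer(k), estimate = k / n, p_value = min(1, p),
    sidedness = if (alternative == "two.sided") "two" else "one",
    method = sprintf("exact binomial test (p0 = %g, %s)", p0, alternative)
  )
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration over all tables with the observed
#' margins. The two-sided p-value sums the probabilities of all tables no
#' more probable than the observed one.
#'
#' @param table A 2x2 matrix (or coercible) of non-negative integer counts.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`
#'   (one-sided alternatives refer to the `[1,1]` cell).
#' @return A one-row tibble: `statistic` (the `[1,1]` count), `p_value`,
#'   `sidedness`, `method`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(14, 2, 1, 19), nrow = 2)) # swim-bladder table
fisher_exact_2x2 <- function(table,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    abort("`table` must be a 2x2 matrix of non-negative integer counts.")
  }
  x <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  N <- sum(tab)
  lo <- max(0, r1 + c1 - N)
  hi <- min(r1, c1)
  support <- lo:hi
  d <- dhyper(support, c1, N - c1, r1)
  obs <- d[support == x]
  p <- switch(alternative,
    two.sided = sum(d[d <= obs * .rel_err]),
    greater = sum(d[support >= x]),
    less = sum(d[support <= x])
  )
  tibble(
    statistic = as.integer(x), p_value = min(1, p),
    sidedness = if (alternative == "two.sided") "two" else "one",
    method = sprintf("Fisher's exact test (%s)", alternative)
  )
}

#' Compare two editing efficiencies by an exact binomial test
#'
#' Tests the group-1 success count against the group-2 rate taken as the
#' null probability: an exact binomial test of `k1` successes in `n1` trials
#' with `p0 = k2 / n2`. This is the construction for comparing e.g.
#' single-guide against paired-guide editing efficiency when only the two
#' count pairs are reported.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2 (define the null rate).
#' @param alternative Passed to [binomial_exact_test()].
#' @return A one-row tibble as from [binomial_exact_test()], with a method
#'   label recording the construction.
#' @export
compare_editing_rates <- function(k1, n1, k2, n2,
                                  alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (n2 < 1 || k2 < 0 || k2 > n2) abort("Group 2 counts are invalid.")
  p0 <- k2 / n2
  if (p0 <= 0 || p0 >= 1) {
    abort("Group 2 rate is degenerate (0 or 1); the binomial null is undefined.")
  }
  out <- binomial_exact_test(k1, n1, p0, alternative)
  out$method <- sprintf(
    "exact binomial test of group-1 count against group-2 rate (%d/%d = %g, %s)",
    k2, n2, p0, alternative
  )
  out
}
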