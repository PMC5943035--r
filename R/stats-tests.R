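#' Wilcoxon rank-sum test
#'
#' Exact two-sided p by complete enumeration of group assignments for
#' combined sample sizes up to 12 (handling ties, with the Mann-Whitney U
#' statistic counting tied pairs as 1/2); the tie-corrected normal
#' approximation of [stats::wilcox.test()] otherwise. The exact two-sided
#' p-value is the probability, over all assignments, of a U at least as far
#' from its null expectation as observed.
#'
#' @param x,y numeric samples
#' @return list with `U` and `p`
#' @export
rank_sum_test <- function(x, y) {
  .assert(length(x) > 0 && length(y) > 0, "both samples must be nonempty")
  nx <- length(x); ny <- length(y)
  u_stat <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  U <- u_stat(x, y)
  if (nx + ny <= 12) {
    pool <- c(x, y)
    idx <- utils::combn(nx + ny, nx)
    EU <- nx * ny / 2
    us <- apply(idx, 2, function(ii) u_stat(pool[ii], pool[-ii]))
    p <- mean(abs(us - EU) >= abs(U - EU) - 1e-12)
  } else if (length(unique(c(x, y))) == 1L) {
    p <- 1 ## all observations tied: no evidence either way
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
  }
  list(U = U, p = p)
}

#' Pearson's chi-squared test on a contingency table
#'
#' @param table matrix of non-negative counts (no continuity correction)
#' @return list with `X2`, `df`, `p`
#' @export
chi_squared_test <- function(table) {
  table <- as.matrix(table)
  .assert(all(table >= 0), "counts must be non-negative")
  .assert(all(rowSums(table) > 0) && all(colSums(table) > 0),
          "table has a zero marginal")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(X2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Pearson correlation with a permutation p-value
#'
#' `p = (1 + #\{permutations with |r*| >= |r|\}) / (n_perm + 1)`, permuting
#' `y` against `x`.
#'
#' @param x,y numeric vectors, `length >= 3`, non-constant
#' @param n_perm number of permutations (default 999)
#' @param seed RNG seed for reproducible permutations
#' @return list with `r` and `p`
#' @export
pearson_corr_permutation <- function(x, y, n_perm = 999L, seed = 1L) {
  .assert(length(x) == length(y) && length(x) >= 3,
          "need paired vectors of length >= 3")
  .assert(sd(x) > 0 && sd(y) > 0, "constant vector: correlation undefined")
  r <- cor(x, y)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (abs(cor(x, sample(y))) >= abs(r) - 1e-12) hits <- hits + 1L
  }
  list(r = r, p = (1 + hits) / (n_perm + 1))
}
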