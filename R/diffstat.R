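#' Median-of-ratios size factors
#'
#' For each individual, the size factor is the median over features of the
#' ratio between that individual's count and the feature's geometric mean
#' across individuals, computed over features with positive counts in every
#' individual.
#'
#' @param matrix features x individuals count matrix
#' @return named numeric vector of positive size factors
#' @export
size_factors <- function(matrix) {
  .assert(is.matrix(matrix) && nrow(matrix) > 0, "need a nonempty matrix")
  allpos <- rowSums(matrix > 0) == ncol(matrix)
  .assert(any(allpos), paste("no feature has positive counts in every",
                             "individual; apply occupancy filtering first"))
  lg <- log(matrix[allpos, , drop = FALSE])
  gm <- rowMeans(lg)
  sf <- apply(exp(lg - gm), 2, median)
  .assert(all(is.finite(sf) & sf > 0), "degenerate size factors")
  sf
}

#' Estimate per-feature negative binomial dispersions
#'
#' Raw dispersions come from pooled within-species method-of-moments on
#' normalized counts (`(var - mu) / mu^2`, averaged over the two species and
#' floored at 1e-8). A mean-dispersion trend `alpha(mu) = a1/mu + a0` is
#' fitted by least squares, and each feature's final dispersion is shrunk
#' geometrically toward the trend: `exp(w log raw + (1-w) log trend)`.
#'
#' @param matrix features x individuals count matrix
#' @param sf size factors from [size_factors()]
#' @param species character vector of `"A"`/`"B"` per column
#' @param w shrinkage weight on the raw estimate (default 0.5)
#' @return a `dispersion_model`: list with `raw`, `trend`, `shrunk`,
#'   `trend_coef`, `w`, `mu`
#' @export
estimate_dispersions <- function(matrix, sf, species, w = 0.5) {
  .assert(min(table(species)) >= 3,
          "need at least 3 individuals per species to estimate dispersion")
  q <- sweep(matrix, 2, sf, "/")
  mu <- rowMeans(q)
  alpha_sp <- sapply(unique(species), function(sp) {
    qs <- q[, species == sp, drop = FALSE]
    m <- rowMeans(qs)
    v <- apply(qs, 1, var)
    (v - m) / m^2
  })
  raw <- rowMeans(alpha_sp, na.rm = TRUE)
  raw[!is.finite(raw)] <- 1e-8
  raw <- pmax(raw, 1e-8)
  fit_on <- which(raw > 1e-8 & mu > 0)
  if (length(fit_on) >= 10) {
    co <- stats::coef(stats::lm(raw[fit_on] ~ I(1 / mu[fit_on])))
    a0 <- co[[1]]; a1 <- co[[2]]
  } else {
    a0 <- max(mean(raw), 1e-8); a1 <- 0
  }
  trend <- pmax(a1 / pmax(mu, 1e-8) + a0, 1e-8)
  shrunk <- exp(w * log(raw) + (1 - w) * log(trend))
  structure(list(raw = raw, trend = trend, shrunk = shrunk,
                 trend_coef = c(a0 = a0, a1 = a1), w = w, mu = mu),
            class = "dispersion_model")
}

## One NB log-link IRLS fit for the two-group design with offsets.
## Returns c(beta0, beta_sp, se_sp, converged).
.nb_irls <- function(y, off, x, alpha, max_iter = 50L, tol = 1e-8) {
  X <- cbind(1, x)
  mu0 <- mean(y / exp(off))
  if (mu0 <= 0) return(c(NA, NA, NA, 0))
  beta <- c(log(mu0), 0)
  for (it in seq_len(max_iter)) {
    eta <- off + X %*% beta
    mu <- pmin(exp(eta), 1e12)
    wt <- as.vector(mu / (1 + alpha * mu))
    z <- as.vector(eta - off + (y - mu) / mu)
    xtw <- t(X * wt)
    fit <- tryCatch(solve(xtw %*% X, xtw %*% z), error = function(e) NULL)
    if (is.null(fit)) return(c(beta, NA, 0))
    delta <- as.vector(fit) - beta
    beta <- as.vector(fit)
    if (max(abs(delta)) < tol) {
      info <- solve(xtw %*% X)
      ## small-sample correction: two coefficients estimated from n samples
      se <- sqrt(info[2, 2] * length(y) / (length(y) - ncol(X)))
      return(c(beta, se, 1))
    }
  }
  c(beta, NA, 0)
}

#' Negative binomial Wald test for a species effect
#'
#' Fits, per feature, the NB regression
#' `log mu_ij = log s_j + beta0 + beta_sp x_j` (with `x_j = 1` for species
#' A) by iteratively reweighted least squares at the shrunken dispersion,
#' and tests `beta_sp = 0` with a two-sided normal Wald p-value. A positive
#' `log2fc` means species A has higher counts.
#'
#' @param matrix features x individuals count matrix
#' @param sf size factors
#' @param disp a `dispersion_model` from [estimate_dispersions()]
#' @param species `"A"`/`"B"` per column
#' @return a data.table (`feature_id`, `base_mean`, `log2fc`, `se`,
#'   `pvalue`, `padj`, `category`) with `padj` from plain BH over tested
#'   features and `category` initialized to `shared`/`not_tested`
#' @export
nb_wald_test <- function(matrix, sf, disp, species) {
  .assert(length(unique(species)) == 2, "species design needs two levels")
  x <- as.numeric(species == "A")
  off <- log(sf)
  n <- nrow(matrix)
  res <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    res[i, ] <- .nb_irls(matrix[i, ], off, x, disp$shrunk[i])
  }
  tested <- !is.na(res[, 4]) & res[, 4] == 1 &
    is.finite(res[, 3]) & res[, 3] > 0
  log2fc <- res[, 2] / log(2)
  se <- res[, 3] / log(2)
  z <- res[, 2] / res[, 3]
  p <- 2 * pnorm(-abs(z))
  p[!tested] <- NA
  out <- data.table::data.table(
    feature_id = if (is.null(rownames(matrix)))
      sprintf("f%05d", seq_len(n)) else rownames(matrix),
    base_mean = rowMeans(sweep(matrix, 2, sf, "/")),
    log2fc = log2fc, se = se, pvalue = p, padj = NA_real_,
    category = ifelse(tested, "shared", "not_tested"))
  out$padj[tested] <- bh_adjust(p[tested])
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate.
#'
#' @param pvalues numeric vector in `[0, 1]`
#' @return adjusted p-values, monotone and capped at 1
#' @export
bh_adjust <- function(pvalues) {
  .assert(is.numeric(pvalues) && all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE),
          "p-values must lie in [0,1]")
  p.adjust(pvalues, method = "BH")
}

#' Independent filtering of low-count features
#'
#' Features with low mean counts have little power and dilute the BH
#' correction. For each base-mean quantile threshold in the grid, BH is
#' applied to the surviving features; the threshold maximizing the number
#' of rejections at `alpha` is kept (smallest threshold on ties), the kept
#' threshold's adjusted p-values are stored, and filtered features are
#' marked `not_tested`.
#'
#' @param results data.table from [nb_wald_test()]
#' @param quantile_grid base-mean quantiles to scan (e.g. `seq(0, 0.4, 0.1)`;
#'   empty grid means no filtering)
#' @param alpha working FDR level (default 0.01)
#' @return the results with `padj` recomputed and `category` updated
#' @export
independent_filter <- function(results, quantile_grid = seq(0, 0.4, 0.1),
                               alpha = 0.01) {
  out <- data.table::copy(results)
  if (!length(quantile_grid)) return(out)
  testable <- out$category != "not_tested" & !is.na(out$pvalue)
  best_n <- -1L; best_keep <- testable
  for (qq in sort(quantile_grid)) {
    thr <- quantile(out$base_mean[testable], qq)
    keep <- testable & out$base_mean >= thr
    if (!any(keep)) next
    nrej <- sum(bh_adjust(out$pvalue[keep]) < alpha)
    if (nrej > best_n) { best_n <- nrej; best_keep <- keep }
  }
  out[, "padj" := NA_real_]
  out$padj[best_keep] <- bh_adjust(out$pvalue[best_keep])
  out[testable & !best_keep, "category" := "not_tested"]
  out
}

#' Classify features into shared and species-enriched categories
#'
#' Features with adjusted p below `alpha` are `A_enriched` or `B_enriched`
#' by the sign of `log2fc`; everything else, including untested features,
#' is `shared`, keeping category proportions on the full retained feature
#' set.
#'
#' @param results data.table with `padj` and `log2fc`
#' @param alpha FDR threshold (default 0.01)
#' @return the results with `category` filled in
#' @export
classify_enrichment <- function(results, alpha = 0.01) {
  out <- data.table::copy(results)
  sig <- !is.na(out$padj) & out$padj < alpha
  out[, "category" := "shared"]
  out[sig & out$log2fc > 0, "category" := "A_enriched"]
  out[sig & out$log2fc < 0, "category" := "B_enriched"]
  out
}

#' Full NB differential analysis
#'
#' Convenience wrapper chaining [size_factors()], [estimate_dispersions()],
#' [nb_wald_test()], [independent_filter()] and [classify_enrichment()];
#' the single engine used for both ChIP region counts and RNA gene counts.
#'
#' @param matrix features x individuals count matrix
#' @param species `"A"`/`"B"` per column
#' @param alpha FDR threshold for classification (default 0.01)
#' @param filter_quantiles grid for [independent_filter()]; `NULL` disables
#' @param w dispersion shrinkage weight
#' @return a classified results data.table
#' @export
nb_differential <- function(matrix, species, alpha = 0.01,
                            filter_quantiles = seq(0, 0.4, 0.1), w = 0.5) {
  sf <- size_factors(matrix)
  disp <- estimate_dispersions(matrix, sf, species, w = w)
  res <- nb_wald_test(matrix, sf, disp, species)
  if (!is.null(filter_quantiles))
    res <- independent_filter(res, filter_quantiles, alpha)
  classify_enrichment(res, alpha)
}
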