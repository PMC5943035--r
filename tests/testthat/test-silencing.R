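fixture_regions <- function() {
  data.table::data.table(
    region_id = c("region001", "region002"),
    chrom_a = "chr1", start_a = c(150L, 1000L), end_a = c(300L, 1400L),
    chrom_b = "chr1", start_b = c(150L, 1000L), end_b = c(300L, 1400L),
    map_a = 1, map_b = 1)
}

fixture_diff <- function() {
  data.table::data.table(
    feature_id = c("region001", "region002"),
    base_mean = c(20, 30), log2fc = c(0.1, 1.5), se = 0.2,
    pvalue = c(0.5, 1e-6), padj = c(0.7, 1e-5),
    category = c("shared", "A_enriched"))
}

fixture_calls <- function(n = 40L, seed = 70L) {
  set.seed(seed)
  data.table::data.table(
    chrom_a = "chr1",
    start_a = as.integer(seq(0, by = 500, length.out = n)),
    end_a = as.integer(seq(0, by = 500, length.out = n)) + 200L,
    name = sample(c("AluY", "L1PA2", "SVA_B", "MER5A"), n, replace = TRUE),
    family = sample(c("Alu", "L1", "SVA", "hAT-Charlie"), n, replace = TRUE),
    te_class = sample(c("SINE", "LINE", "SVA", "DNA"), n, replace = TRUE),
    milli_div = runif(n, 10, 300),
    status = sample(c("shared", "A_enriched", "B_enriched",
                      "non_overlapping"), n, replace = TRUE),
    region_log2fc = rnorm(n))
}

test_that("the 50 percent length rule splits at the exact boundary", {
  tes <- data.table::data.table(
    chrom_a = "chr1", start_a = c(100L, 100L), end_a = c(200L, 200L),
    name = "AluY", te_class = "SINE", family = "Alu", milli_div = 50)
  ## region [150,300) covers exactly half of [100,200): overlapping
  r <- fixture_regions()
  calls <- classify_te_silencing(tes[1], r[1], fixture_diff()[1])
  expect_equal(calls$overlap_fraction, 0.5)
  expect_identical(calls$status, "shared")
  ## one bp less coverage: non-overlapping
  r2 <- data.table::copy(r[1])
  r2$start_a <- 151L
  calls2 <- classify_te_silencing(tes[1], r2, fixture_diff()[1])
  expect_lt(calls2$overlap_fraction, 0.5)
  expect_identical(calls2$status, "non_overlapping")
})

test_that("TEs inherit the category of the largest-overlap region", {
  regions <- data.table::data.table(
    region_id = c("region001", "region002"),
    chrom_a = "chr1", start_a = c(100L, 300L), end_a = c(300L, 500L),
    chrom_b = "chr1", start_b = c(100L, 300L), end_b = c(300L, 500L),
    map_a = 1, map_b = 1)
  diff <- fixture_diff()
  tes <- data.table::data.table(
    chrom_a = "chr1", start_a = 100L, end_a = 500L,
    name = "L1PA2", te_class = "LINE", family = "L1", milli_div = 120)
  ## 200 bp overlap with each region: tie broken toward the smaller id
  calls <- classify_te_silencing(tes, regions, diff)
  expect_identical(calls$assigned_region, "region001")
  expect_identical(calls$status, "shared")
  ## shrink the left overlap so region002 wins
  tes$start_a <- 150L
  calls2 <- classify_te_silencing(tes, regions, diff)
  expect_identical(calls2$assigned_region, "region002")
  expect_identical(calls2$status, "A_enriched")
})

test_that("silencing categories partition the TE set and respect min_frac", {
  cohort <- small_cohort(seed = 44L)
  ortho <- orthologous_te_set(cohort$tes$rmsk_a, cohort$tes$rmsk_b,
                              cohort$gp$chain_ab, cohort$gp$chain_ba)
  regions <- data.table::data.table(
    region_id = sprintf("region%03d", 1:50),
    chrom_a = sample(c("chr1", "chr2"), 50, replace = TRUE),
    start_a = as.integer(seq(1000, by = 3500, length.out = 50)))
  regions$end_a <- regions$start_a + 600L
  regions$chrom_b <- regions$chrom_a
  regions$start_b <- regions$start_a; regions$end_b <- regions$end_a
  diff <- data.table::data.table(
    feature_id = regions$region_id, base_mean = 10,
    log2fc = rnorm(50), se = 0.3, pvalue = runif(50),
    padj = runif(50), category = sample(c("shared", "A_enriched",
                                          "B_enriched"), 50, TRUE))
  calls <- classify_te_silencing(ortho, regions, diff, min_frac = 0.5)
  expect_identical(nrow(calls), nrow(ortho))
  expect_true(all(calls$status %in% c("non_overlapping", "shared",
                                      "A_enriched", "B_enriched")))
  expect_true(all((calls$status != "non_overlapping") ==
                    (calls$overlap_fraction >= 0.5)))
  ## monotone in min_frac: raising it never adds overlapping TEs
  strict <- classify_te_silencing(ortho, regions, diff, min_frac = 0.8)
  expect_true(all(which(strict$status != "non_overlapping") %in%
                    which(calls$status != "non_overlapping")))
})

test_that("class enrichment tables match a hand tally", {
  calls <- data.table::data.table(
    te_class = rep(c("SVA", "DNA"), each = 10),
    family = rep(c("SVA", "hAT-Charlie"), each = 10),
    status = c(rep("shared", 8), rep("non_overlapping", 2),
               rep("shared", 1), rep("non_overlapping", 9)))
  out <- enrichment_by_class(calls)
  sva <- out[out$te_class == "SVA"]
  expect_equal(sva$prop_overlap, 0.8)
  expect_equal(sva$background_prop, 0.1)
  expect_identical(sva$direction, "enriched")
  hand <- chi_squared_test(rbind(c(8, 2), c(1, 9)))
  expect_equal(sva$X2, hand$X2)
  dna <- out[out$te_class == "DNA"]
  expect_identical(dna$direction, "depleted")
})

test_that("class-specific priors surface as enrichment and depletion", {
  cohort <- small_cohort(
    seed = 46L,
    te_silencing_prior = c(LINE = 0.2, SINE = 0.2, LTR = 0.2, DNA = 0.1,
                           SVA = 0.6))
  tr <- cohort$tes$truth
  calls <- data.table::data.table(
    te_class = tr$te_class, family = tr$family,
    status = ifelse(tr$silencing_label == "none", "non_overlapping",
                    "shared"))
  out <- enrichment_by_class(calls)
  expect_identical(out$direction[out$te_class == "SVA"], "enriched")
  expect_identical(out$direction[out$te_class == "DNA"], "depleted")
})

test_that("length-matched extension conserves count and reaches the target", {
  set.seed(47)
  te <- data.table::data.table(
    chrom_a = "chr1",
    start_a = as.integer(runif(200, 1000, 90000)))
  te$end_a <- te$start_a + sample(100:300, 200, TRUE)
  regions <- data.table::data.table(
    region_id = sprintf("r%02d", 1:30), chrom_a = "chr1",
    start_a = as.integer(runif(30, 0, 95000)))
  regions$end_a <- regions$start_a + 2000L
  lens <- c(chr1 = 100000L)
  out <- length_matched_control(te, regions, target_median = 1000L,
                                chrom_lens = lens)
  expect_identical(nrow(out$extended_tes), nrow(te))
  expect_equal(median(out$extended_tes$end_a - out$extended_tes$start_a),
               1000)
  ## extending to the current median changes nothing
  tm <- as.integer(ceiling(median(te$end_a - te$start_a)))
  out0 <- length_matched_control(te, regions, target_median = tm,
                                 chrom_lens = lens)
  expect_gte(out0$extended, out0$original)
  ## with independent random regions the change stays within 3 binomial SE
  ## of the longer-length expectation difference; coarse sanity bound
  expect_lt(abs(out$extended - out$original), 0.5)
})

test_that("property comparison contrasts shared vs non-overlapping", {
  calls <- fixture_calls(200)
  ## identical groups: p cannot be small
  calls$milli_div <- 100
  pc <- property_compare(calls, "milli_div", "category")
  expect_gte(pc$tests$p[1], 0.5)
  ## construct longer shared TEs
  calls2 <- fixture_calls(400)
  long <- calls2$status == "shared"
  calls2$end_a <- calls2$start_a +
    ifelse(long, 300L, 200L) + sample(0:20, 400, TRUE)
  pc2 <- property_compare(calls2, "length", "category")
  expect_lt(pc2$tests$p[1], 0.01)
  med <- pc2$summary
  expect_gt(med$median[med$group == "shared"],
            med$median[med$group == "non_overlapping"])
  ## tss distance: a TE ending 1 bp before a TSS is at distance 1
  one <- data.table::data.table(
    chrom_a = "chr1", start_a = 100L, end_a = 200L, name = "AluY",
    te_class = "SINE", family = "Alu", milli_div = 10,
    status = "shared", region_log2fc = 0.1)
  pc3 <- property_compare(one, "tss_distance", "category",
                          tss = data.table::data.table(chrom = "chr1",
                                                       tss = 201L))
  expect_equal(pc3$summary$median, 1)
})

test_that("annotation overlap distinguishes the two intersection modes", {
  calls <- data.table::data.table(
    chrom_a = "chr1", start_a = 0L, end_a = 100L, status = "shared")
  ann <- gi("chr1", 99, 200)
  hit_any <- annotate_overlap(calls, ann, mode = "any_bp")
  expect_equal(hit_any$proportions$proportion, 1)
  hit_half <- annotate_overlap(calls, ann, mode = "half_length")
  expect_equal(hit_half$proportions$proportion, 0)
  ## whole-genome annotation hits everything in both modes
  whole <- gi("chr1", 0, 2e6)
  calls2 <- fixture_calls(50)
  for (mode in c("any_bp", "half_length")) {
    out <- annotate_overlap(calls2, whole, mode = mode)
    expect_true(all(out$proportions$proportion == 1))
  }
  ## proportions match a brute-force per-TE scan
  set.seed(48)
  ann2 <- gi("chr1", sort(sample(0:20000, 20)) * 1L,
             sort(sample(0:20000, 20)) + 500L)
  calls3 <- fixture_calls(500)
  out3 <- annotate_overlap(calls3, ann2, mode = "half_length")
  brute <- vapply(seq_len(nrow(calls3)), function(i) {
    iv <- IRanges::IRanges(calls3$start_a[i] + 1L, calls3$end_a[i])
    cov <- sum(IRanges::width(IRanges::intersect(
      iv, IRanges::reduce(IRanges::ranges(ann2)))))
    cov >= 0.5 * IRanges::width(iv)
  }, logical(1))
  tab <- data.table::data.table(status = calls3$status, hit = brute)
  want <- tab[, list(proportion = mean(hit)), by = "status"]
  got <- merge(out3$proportions, want, by = "status")
  expect_equal(got$proportion.x, got$proportion.y)
})

test_that("copy-number correlation runs and fails cleanly when degenerate", {
  calls <- fixture_calls(300)
  out <- copy_number_vs_overlap(calls, n_perm = 199, seed = 3)
  expect_true(abs(out$r) <= 1)
  out2 <- copy_number_vs_overlap(calls, n_perm = 199, seed = 3)
  expect_identical(out$p, out2$p)
  flat <- data.table::copy(calls)[, "status" := "shared"]
  expect_error(copy_number_vs_overlap(flat, n_perm = 99, seed = 1),
               "constant")
})
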