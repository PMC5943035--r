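test_that("TSS selection follows strand-aware transcript choice", {
  expect_equal(select_tss(c(100, 150), "+"), 100)
  expect_equal(select_tss(c(100, 150), "-"), 150)
  expect_equal(select_tss(42, "+"), 42)
  expect_error(select_tss(numeric(0), "+"), "no transcripts")
})

test_that("upstream windows exclude the TSS base and clip at ends", {
  w <- upstream_window(5000, "+", 1000, 100000)
  expect_equal(GenomicRanges::start(w) - 1L, 4000)
  expect_equal(GenomicRanges::end(w), 5000)
  w2 <- upstream_window(5000, "-", 1000, 100000)
  expect_equal(GenomicRanges::start(w2) - 1L, 5000)
  expect_equal(GenomicRanges::end(w2), 6000)
  w3 <- upstream_window(500, "+", 1000, 100000)
  expect_equal(GenomicRanges::start(w3) - 1L, 0)
  expect_equal(GenomicRanges::end(w3), 500)
  ## plus and minus windows are mirror images on a reflected coordinate
  L <- 100000
  wp <- upstream_window(5000, "+", 1000, L)
  wm <- upstream_window(L - 5000, "-", 1000, L)
  expect_equal(GenomicRanges::start(wp) - 1L, L - GenomicRanges::end(wm))
  expect_error(upstream_window(-5, "+", 1000, 100), "outside")
})

test_that("gene-level silencing counts each region once per gene", {
  ## 3 genes, 4 regions, 5 TEs; hand-tallied expectations
  genes <- data.table::data.table(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1", strand = "+",
    tss = c(10000L, 20000L, 30000L))
  tes <- data.table::data.table(
    chrom_a = "chr1",
    start_a = c(9000L, 9400L, 19000L, 19500L, 50000L),
    end_a = c(9200L, 9600L, 19200L, 19700L, 50200L))
  regions <- data.table::data.table(
    region_id = c("r1", "r2", "r3", "r4"),
    chrom_a = "chr1",
    start_a = c(8900L, 19100L, 19400L, 60000L),
    end_a = c(9700L, 19300L, 19800L, 60500L))
  regions$chrom_b <- regions$chrom_a
  regions$start_b <- regions$start_a; regions$end_b <- regions$end_a
  counts <- matrix(c(5L, 7L, 3L, 9L, 6L, 8L, 4L, 10L,
                     2L, 3L, 1L, 4L, 3L, 4L, 2L, 5L,
                     7L, 9L, 5L, 11L, 8L, 10L, 6L, 12L),
                   nrow = 4,
                   dimnames = list(c("r1", "r2", "r3", "r4"),
                                   sprintf("%s%02d", rep(c("A", "B"), 3),
                                           rep(1:3, each = 2))))
  ## need >= 3 per species for the NB engine: replicate columns
  counts <- cbind(counts, counts[, 1:2] + 1L)
  colnames(counts) <- sprintf("%s0%d", rep(c("A", "B"), 4), rep(1:4, each = 2))
  attr(counts, "species") <- setNames(rep(c("A", "B"), 4), colnames(counts))
  out <- gene_silencing_counts(genes, 1000L, tes, regions, counts,
                               c(chr1 = 100000L))
  ## g1 window [9000,10000): TEs 1,2 in r1 only -> r1 counted once
  ## g2 window [19000,20000): TEs 3,4 hit r2 and r3 -> r2 + r3
  ## g3 window [29000,30000): no TE -> excluded
  expect_identical(sort(rownames(out$counts)), c("g1", "g2"))
  expect_identical(unname(out$counts["g1", ]), unname(counts["r1", ]))
  expect_identical(unname(out$counts["g2", ]),
                   unname(counts["r2", ] + counts["r3", ]))
  expect_identical(out$n_regions_used[["g1"]], 1L)
  expect_identical(out$n_regions_used[["g2"]], 2L)
  expect_identical(sort(out$diff$feature_id), c("g1", "g2"))
})

test_that("expression occupancy filter applies the >10/17 ratio", {
  m <- matrix(0L, nrow = 3, ncol = 17,
              dimnames = list(c("keep11", "drop10", "drop0"),
                              sprintf("%s%02d", rep(c("A", "B"), c(10, 7)),
                                      1:17)))
  m["keep11", 1:11] <- 5L
  m["drop10", 1:10] <- 5L
  sp <- setNames(rep(c("A", "B"), c(10, 7)), colnames(m))
  out <- filter_and_normalize_expression(m, sp)
  expect_identical(rownames(out$filtered), "keep11")
  ## the ratio generalizes: 20 individuals keep > 11
  m20 <- matrix(0L, nrow = 2, ncol = 20,
                dimnames = list(c("keep12", "drop11"), sprintf("i%02d", 1:20)))
  m20["keep12", 1:12] <- 1L
  m20["drop11", 1:11] <- 1L
  out20 <- filter_and_normalize_expression(
    m20, setNames(rep(c("A", "B"), each = 10), colnames(m20)))
  expect_identical(rownames(out20$filtered), "keep12")
})

test_that("quantile normalization maps columns onto the mean quantiles", {
  m <- cbind(a1 = c(1, 2, 3), b1 = c(4, 5, 6),
             a2 = c(1, 2, 3), b2 = c(4, 5, 6))
  rownames(m) <- c("g1", "g2", "g3")
  out <- filter_and_normalize_expression(
    m, setNames(c("A", "B", "A", "B"), colnames(m)))
  for (j in colnames(m))
    expect_equal(unname(out$qnorm[, j]), c(2.5, 3.5, 4.5))
  ## identical columns: quantile normalization is the identity
  mi <- matrix(rep(c(3, 9, 27, 81), 4), ncol = 4,
               dimnames = list(sprintf("h%d", 1:4), c("x", "y", "z", "w")))
  oi <- filter_and_normalize_expression(
    mi, setNames(c("A", "B", "A", "B"), colnames(mi)))
  expect_equal(unname(oi$qnorm), unname(mi))
})

test_that("TE-type RPKM applies the strict expression threshold", {
  out <- te_type_rpkm(c(5000, 500, 2500), c(250000, 250000, 250000), 1e7)
  expect_equal(out$rpkm, c(2.0, 0.2, 1.0))
  expect_identical(out$expressed, c(TRUE, FALSE, FALSE))
  expect_error(te_type_rpkm(10, 0, 1e7), "positive")
  expect_error(te_type_rpkm(10, 100, 0), "positive")
})

test_that("gene-set overlap modes follow the half-coverage rules", {
  genes <- data.table::data.table(
    gene_id = c("znf1", "znf2", "znf3"), chrom = "chr1", strand = "+",
    tss = c(1000L, 5000L, 9000L),
    tx_start = c(1000L, 5000L, 9000L), tx_end = c(3000L, 6000L, 9800L))
  regions <- data.table::data.table(
    region_id = c("r1", "r2"), chrom_a = "chr1",
    start_a = c(500L, 4499L), end_a = c(3500L, 4999L))
  regions$chrom_b <- regions$chrom_a
  regions$start_b <- regions$start_a; regions$end_b <- regions$end_a
  diff <- data.table::data.table(
    feature_id = c("r1", "r2"), base_mean = 10, log2fc = c(2, -2),
    se = 0.2, pvalue = c(1e-5, 1e-5), padj = c(1e-4, 1e-4),
    category = c("A_enriched", "B_enriched"))
  body <- gene_set_h3k9me3_overlap(c("znf1", "znf2", "nope"), genes,
                                   regions, diff, mode = "body_half")
  expect_identical(body$unknown, "nope")
  expect_identical(body$flags$overlapping, c(TRUE, FALSE))
  expect_identical(body$flags$category[1], "A_enriched")
  ## r2 covers [4499,4999): 499 bp of znf2's 1 kb TSS window [4500,5500)
  tss <- gene_set_h3k9me3_overlap("znf2", genes, regions, diff,
                                  mode = "tss_1kb_half")
  expect_false(tss$flags$overlapping)
  ## brute-force coverage agreement on the full set
  tssall <- gene_set_h3k9me3_overlap(genes$gene_id, genes, regions, diff,
                                     mode = "tss_1kb_half")
  brute <- vapply(seq_len(nrow(genes)), function(i) {
    iv <- IRanges::IRanges(genes$tss[i] - 500L + 1L, genes$tss[i] + 500L)
    red <- IRanges::reduce(IRanges::IRanges(regions$start_a + 1L,
                                            regions$end_a))
    sum(IRanges::width(IRanges::intersect(iv, red))) >= 500
  }, logical(1))
  expect_identical(tssall$flags$overlapping, brute)
})

test_that("non-orthologous TE silencing labels genes silent only when all overlap", {
  tes <- list(A = data.table::data.table(
    chrom = "chr1", start = c(800L, 900L, 4800L, 4900L),
    end = c(880L, 980L, 4880L, 4980L)))
  peaks <- list(A = gi("chr1", c(790, 880), c(890, 990)), B = NULL)
  ## gene g1: both upstream TEs covered >= 50% -> silent
  ## gene g2: neither covered -> non-silent; g3 has no TEs -> excluded
  genes <- list(A = data.table::data.table(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1", strand = "+",
    tss = c(1000L, 5000L, 9000L)))
  de <- data.table::data.table(
    feature_id = c("g1", "g2", "g3"), base_mean = 10,
    log2fc = c(0.1, 2, 0.5), se = 0.2, pvalue = 0.5, padj = 0.9,
    category = "shared")
  ## need at least 2 genes per label for the rank-sum: replicate the fixture
  tes$A <- rbind(tes$A, data.table::copy(tes$A)[, c("start", "end") :=
                                                  list(start + 20000L,
                                                       end + 20000L)])
  genes$A <- rbind(genes$A,
                   data.table::copy(genes$A)[, "tss" := tss + 20000L][,
                     "gene_id" := c("g4", "g5", "g6")])
  peaks$A <- c(peaks$A, gi("chr1", c(20790, 20880), c(20890, 20990)))
  de <- rbind(de, data.table::copy(de)[, "feature_id" := c("g4", "g5", "g6")])
  out <- nonorthologous_te_association(tes, peaks, genes, 1000L, de,
                                       list(A = c(chr1 = 1e5),
                                            B = c(chr1 = 1e5)))
  expect_identical(out$n_silent, 2L)
  expect_identical(out$n_non_silent, 2L)
  expect_true(out$median_non_silent > out$median_silent)
})

test_that("association of silencing with expression detects coupling", {
  set.seed(60)
  ng <- 200
  sp <- rep(c("A", "B"), each = 8)
  ## silencing counts: 30 genes A-enriched, 30 B-enriched silencing
  mu <- rlnorm(ng, log(60), 0.5)
  eff <- c(rep(2, 30), rep(-2, 30), rep(0, ng - 60))
  sil <- matrix(rnbinom(ng * 16, mu = outer(mu, rep(1, 16)) *
                          2^outer(eff / 2, ifelse(sp == "A", 1, -1)),
                        size = 8), nrow = ng,
                dimnames = list(sprintf("g%03d", 1:ng), sprintf("i%02d", 1:16)))
  sil_diff <- nb_differential(sil, sp, filter_quantiles = NULL)
  ## expression anti-coupled to the silencing effect
  emu <- rlnorm(ng, log(100), 0.5)
  eexp <- -0.8 * eff + rnorm(ng, 0, 0.1)
  ex <- matrix(rnbinom(ng * 16, mu = outer(emu, rep(1, 16)) *
                         2^outer(eexp / 2, ifelse(sp == "A", 1, -1)),
                       size = 8), nrow = ng, dimnames = dimnames(sil))
  ex_diff <- nb_differential(ex, sp, filter_quantiles = NULL)
  out <- silencing_expression_association(sil_diff, ex_diff,
                                          n_perm = 499, seed = 2)
  expect_lt(out$correlation$r, -0.3)
  expect_lte(out$correlation$p, 0.01)
  expect_gt(out$sign_consistency[["opposite"]],
            out$sign_consistency[["same"]])
  ## genes present in only one input are excluded
  out2 <- silencing_expression_association(sil_diff[1:100], ex_diff,
                                           n_perm = 99, seed = 2)
  expect_identical(nrow(out2$merged), 100L)
})
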