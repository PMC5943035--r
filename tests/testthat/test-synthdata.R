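test_that("invalid configurations are rejected before any compute", {
  expect_error(sim_config(chrom_len = -5), "chrom_len")
  expect_error(sim_config(substitution_rate = 1.4), "substitution_rate")
  expect_error(sim_config(te_class_weights = c(LINE = 1, SINE = 0.5,
                                               LTR = 0, DNA = 0, SVA = 0)),
               "summing to 1")
  expect_error(sim_config(n_individuals_per_species = c(A = 0L, B = 3L)),
               "counts >= 1")
})

test_that("zero mutation rates give identical genomes and one-block chains", {
  cfg <- sim_config(seed = 2L, n_chrom = 2L, chrom_len = 5e4,
                    substitution_rate = 0, indel_rate = 0, n_te = 50L,
                    n_individuals_per_species = c(A = 2L, B = 2L),
                    n_genes = 5L)
  gp <- simulate_genome_pair(cfg)
  expect_identical(as.character(gp$genome_a), as.character(gp$genome_b))
  expect_true(all(vapply(gp$chain_ab, function(ch) nrow(ch$blocks),
                         integer(1)) == 1L))
  expect_identical(gp$chain_ab[[1]]$blocks$size, 50000L)
  expect_identical(nrow(gp$event_log), 0L)
})

test_that("chain blocks track realized indel events", {
  cfg <- sim_config(seed = 8L, n_chrom = 1L, chrom_len = 2e5,
                    indel_rate = 5e-4, n_te = 50L,
                    n_individuals_per_species = c(A = 2L, B = 2L),
                    n_genes = 5L)
  gp <- simulate_genome_pair(cfg)
  n_indels <- nrow(gp$event_log)
  expect_gt(n_indels, 0)
  ## every indel breaks at most one block; blocks <= 1 + indels, and the
  ## chain must carry at least a block per unbroken stretch
  n_blocks <- nrow(gp$chain_ab[[1]]$blocks)
  expect_gte(n_blocks, 1)
  expect_lte(n_blocks, 1 + n_indels)
  expect_gte(n_blocks, 1 + n_indels - sum(gp$event_log$len > 1) -
               n_indels %/% 2)
})

test_that("the same seed reproduces byte-identical artifacts", {
  cfg <- sim_config(seed = 3L, n_chrom = 1L, chrom_len = 3e4, n_te = 60L,
                    n_individuals_per_species = c(A = 2L, B = 2L),
                    n_genes = 8L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     info = f)
  }
})

test_that("TE tables honour the configured composition", {
  cfg <- sim_config(seed = 4L, n_chrom = 2L, chrom_len = 1e6, n_te = 5000L,
                    n_individuals_per_species = c(A = 2L, B = 2L),
                    n_genes = 5L)
  gp <- simulate_genome_pair(cfg)
  tes <- simulate_te_annotations(cfg, gp)
  ## realized class proportions within 3 binomial SE of the weights
  tab <- table(tes$truth$te_class)[names(cfg$te_class_weights)]
  n <- nrow(tes$truth)
  for (cl in names(cfg$te_class_weights)) {
    p <- cfg$te_class_weights[[cl]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(tab[[cl]] / n - p), 3 * se + 1e-9)
  }
  ## instances never overlap within a table and stay inside chromosomes
  for (tb in list(tes$rmsk_a, tes$rmsk_b)) {
    ord <- tb[order(chrom, start)]
    same <- ord$chrom[-1] == ord$chrom[-nrow(ord)]
    expect_true(all(ord$start[-1][same] >= ord$end[-nrow(ord)][same]))
    expect_true(all(ord$start >= 0))
  }
  ## silencing labels within 3 SE of the per-class prior
  orth <- tes$truth[tes$truth$orthology_label == "orthologous"]
  for (cl in c("SVA", "LINE")) {
    p <- cfg$te_silencing_prior[[cl]]
    x <- orth$silencing_label[orth$te_class == cl] != "none"
    expect_lt(abs(mean(x) - p), 3 * sqrt(p * (1 - p) / length(x)))
  }
})

test_that("species-specific rate zero puts every TE name in both tables", {
  cfg <- sim_config(seed = 6L, n_chrom = 1L, chrom_len = 2e5, n_te = 300L,
                    species_specific_te_rate = 0,
                    n_individuals_per_species = c(A = 2L, B = 2L),
                    n_genes = 5L)
  tes <- simulate_te_annotations(cfg, simulate_genome_pair(cfg))
  expect_true(all(tes$rmsk_a$name %in% tes$rmsk_b$name))
  expect_true(all(tes$rmsk_b$name %in% tes$rmsk_a$name))
})

test_that("a zero SVA class weight yields zero SVA rows", {
  cfg <- sim_config(seed = 6L, n_chrom = 1L, chrom_len = 2e5, n_te = 300L,
                    te_class_weights = c(LINE = 0.35, SINE = 0.40,
                                         LTR = 0.15, DNA = 0.10, SVA = 0),
                    n_individuals_per_species = c(A = 2L, B = 2L),
                    n_genes = 5L)
  tes <- simulate_te_annotations(cfg, simulate_genome_pair(cfg))
  expect_identical(sum(tes$rmsk_a$te_class == "SVA"), 0L)
  expect_identical(sum(tes$rmsk_b$te_class == "SVA"), 0L)
})

test_that("orthologous TE coordinates correspond under the chains", {
  cohort <- small_cohort(seed = 21L)
  tr <- cohort$tes$truth[cohort$tes$truth$orthology_label == "orthologous"]
  r <- k9te:::.lift_many(tr$chrom, tr$start_a, tr$end_a,
                         cohort$gp$chain_ab, 0.5)
  ok <- which(r$ok)
  expect_gt(length(ok), 0.9 * nrow(tr))
  ## lifted genome-A spans match the genome-B annotation almost exactly
  expect_true(all(abs(r$t_start[ok] - tr$start_b[ok]) <= 5))
})

test_that("with no silencing, ChIP is indistinguishable from Input", {
  cfg <- sim_config(seed = 12L, n_chrom = 1L, chrom_len = 2e5, n_te = 200L,
                    te_silencing_prior = c(LINE = 0, SINE = 0, LTR = 0,
                                           DNA = 0, SVA = 0),
                    n_individuals_per_species = c(A = 2L, B = 2L),
                    n_genes = 5L)
  gp <- simulate_genome_pair(cfg)
  tes <- simulate_te_annotations(cfg, gp)
  fr <- simulate_chip_fragments(cfg, gp, tes)
  chip_mid <- (fr$chip[["A01"]]$start + fr$chip[["A01"]]$end) / 2
  input_mid <- (fr$input[["A01"]]$start + fr$input[["A01"]]$end) / 2
  ks <- suppressWarnings(stats::ks.test(chip_mid, input_mid))
  expect_gt(ks$p.value, 0.01)
})

test_that("species-specific silencing shows the configured density ratio", {
  cfg <- sim_config(seed = 13L, n_chrom = 2L, chrom_len = 5e5, n_te = 2000L,
                    species_effect_log2fc = 2,
                    n_individuals_per_species = c(A = 6L, B = 6L),
                    n_genes = 5L)
  gp <- simulate_genome_pair(cfg)
  tes <- simulate_te_annotations(cfg, gp)
  fr <- simulate_chip_fragments(cfg, gp, tes)
  tr <- tes$truth
  count_over <- function(lab, which_sp) {
    sel <- tr$silencing_label == lab & tr$present_a & tr$present_b
    gr_a <- gi(tr$chrom[sel], tr$start_a[sel], tr$end_a[sel])
    gr_b <- gi(tr$chrom[sel], tr$start_b[sel], tr$end_b[sel])
    inds <- names(fr$species)[fr$species == which_sp]
    total <- 0
    for (ind in inds) {
      frg <- fr$chip[[ind]]
      gr <- if (which_sp == "A") gr_a else gr_b
      total <- total + sum(GenomicRanges::countOverlaps(
        gr, gi(frg$chrom, frg$start, frg$end)))
    }
    total / length(inds)
  }
  ratio <- count_over("speciesA_only", "A") / count_over("speciesA_only", "B")
  expect_gt(ratio, 2^2 * 0.7)
  expect_lt(ratio, 2^2 * 1.4)
  ## shared TEs are enriched in both species relative to background
  shared_a <- count_over("shared", "A")
  sel_none <- tr$silencing_label == "none" & tr$present_a
  bg_gr <- gi(tr$chrom[sel_none], tr$start_a[sel_none], tr$end_a[sel_none])
  frg <- fr$chip[["A01"]]
  bg_rate <- sum(GenomicRanges::countOverlaps(
    bg_gr, gi(frg$chrom, frg$start, frg$end))) / length(bg_gr)
  expect_gt(shared_a / sum(tr$silencing_label == "shared" & tr$present_a &
                             tr$present_b), bg_rate)
})

test_that("expression coupling drives the true gene effects", {
  cfg <- sim_config(seed = 14L, n_chrom = 2L, chrom_len = 5e5, n_te = 2000L,
                    expression_coupling = -1,
                    n_individuals_per_species = c(A = 8L, B = 8L),
                    n_genes = 300L)
  gp <- simulate_genome_pair(cfg)
  tes <- simulate_te_annotations(cfg, gp)
  ex <- simulate_expression(cfg, gp, tes)
  gt <- ex$gene_truth
  cpl_a <- gt$coupled & gt$direction == 1
  expect_gt(sum(cpl_a), 5)
  expect_equal(mean(gt$effect[cpl_a]), -1, tolerance = 1e-9)
  ## uncoupled genes follow the centred null
  expect_lt(abs(mean(gt$effect[!gt$coupled])),
            3 * cfg$expression_null_sd / sqrt(sum(!gt$coupled)) + 0.01)
  ## for effect-free genes the two species' count means agree within noise
  null_genes <- which(!gt$coupled & abs(gt$effect) < 0.02)
  expect_gt(length(null_genes), 10)
  a <- rowMeans(ex$counts[null_genes, ex$species == "A", drop = FALSE])
  b <- rowMeans(ex$counts[null_genes, ex$species == "B", drop = FALSE])
  lr <- log2((a + 1) / (b + 1))
  expect_lt(abs(mean(lr)), 3 * sd(lr) / sqrt(length(lr)) + 0.05)
  expect_identical(dim(ex$counts), c(cfg$n_genes, 16L))
})
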