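## Gene and expression simulation. Genes are placed in genome-A coordinates
## with a strand and 1-3 transcripts; expression counts are negative
## binomial per gene x individual. Genes with a species-specifically
## silenced TE in the configured upstream window receive a true expression
## species effect of expression_coupling x (silencing direction); all other
## genes draw their effect from a centred null distribution.

#' Simulate gene models and expression counts
#'
#' @param cfg a [sim_config()]
#' @param gp output of [simulate_genome_pair()]
#' @param tes output of [simulate_te_annotations()]
#' @return a list with `genes` (transcript table), `gene_table` (one row per
#'   gene with selected TSS), `counts` (gene x individual integer matrix),
#'   `species`, `gene_truth` (true log2 species effects and coupling
#'   status), `te_type_reads` (per-type per-species read totals and
#'   agglomerated lengths) and `total_exonic_reads`
#' @export
simulate_expression <- function(cfg, gp, tes) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 3000L)
  n_a <- cfg$n_individuals_per_species[["A"]]
  n_b <- cfg$n_individuals_per_species[["B"]]
  inds <- c(sprintf("A%02d", seq_len(n_a)), sprintf("B%02d", seq_len(n_b)))
  species <- setNames(rep(c("A", "B"), c(n_a, n_b)), inds)
  lens_a <- setNames(Biostrings::width(gp$genome_a), names(gp$genome_a))
  ng <- cfg$n_genes
  gene_id <- sprintf("gene%04d", seq_len(ng))
  chrom <- sample(names(lens_a), ng, replace = TRUE,
                  prob = lens_a / sum(lens_a))
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  glen <- as.integer(pmin(20000, pmax(1000, round(rlnorm(ng, log(4000), 0.6)))))
  tx_start <- floor(runif(ng) * pmax(1, lens_a[chrom] - glen - 1))
  n_tx <- sample(1:3, ng, replace = TRUE)
  tx <- data.table::data.table(
    gene_id = rep(gene_id, n_tx),
    chrom = rep(chrom, n_tx),
    strand = rep(strand, n_tx))
  off <- floor(runif(nrow(tx)) * 500)
  tx$tx_start <- as.integer(rep(tx_start, n_tx) + off)
  tx$tx_end <- as.integer(rep(tx_start + glen, n_tx))

  gene_table <- tx[, list(chrom = chrom[1], strand = strand[1],
                          tss = select_tss(tx_start, strand[1]),
                          tx_start = min(tx_start), tx_end = max(tx_end)),
                   by = "gene_id"]

  ## upstream coupling: species-specifically silenced TEs (genome-A coords)
  truth <- tes$truth[tes$truth$present_a == TRUE &
                       tes$truth$silencing_label %in%
                       c("speciesA_only", "speciesB_only")]
  direction <- numeric(ng)
  if (nrow(truth)) {
    te_gr <- gi(truth$chrom, truth$start_a, truth$end_a)
    win <- .upstream_windows(gene_table$tss, gene_table$strand,
                             cfg$coupling_window,
                             lens_a[gene_table$chrom], gene_table$chrom)
    ov <- GenomicRanges::findOverlaps(win$gr, te_gr)
    if (length(ov)) {
      d <- ifelse(truth$silencing_label == "speciesA_only", 1, -1)
      agg <- tapply(d[S4Vectors::subjectHits(ov)],
                    S4Vectors::queryHits(ov), sum)
      direction[win$idx[as.integer(names(agg))]] <- sign(agg)
    }
  }
  coupled <- direction != 0
  effect <- rnorm(ng, 0, cfg$expression_null_sd)
  effect[coupled] <- cfg$expression_coupling * direction[coupled]

  base <- rlnorm(ng, log(100), 1)
  sf <- setNames(rlnorm(length(inds), 0, 0.1), inds)
  mu <- outer(base, sf) *
    2^(outer(effect / 2, ifelse(species == "A", 1, -1)))
  counts <- matrix(rnbinom(length(mu), mu = mu,
                           size = if (cfg$nb_dispersion > 0)
                             1 / cfg$nb_dispersion else 1e8),
                   nrow = ng, dimnames = list(gene_id, inds))

  ## per-TE-type agglomerated expression
  rmsk <- list(A = tes$rmsk_a, B = tes$rmsk_b)
  total_exonic <- setNames(round(c(1e7, 1e7) * rlnorm(2, 0, 0.05)),
                           c("A", "B"))
  type_reads <- data.table::rbindlist(lapply(c("A", "B"), function(sp) {
    tab <- rmsk[[sp]][, list(agg_len = sum(end - start)), by = "name"]
    expressed <- runif(nrow(tab)) < 0.2
    rpkm_true <- ifelse(expressed, runif(nrow(tab), 1.5, 10),
                        runif(nrow(tab), 0, 0.5))
    tab$reads <- rpois(nrow(tab),
                       rpkm_true * tab$agg_len * total_exonic[[sp]] / 1e9)
    tab$species <- sp
    tab
  }))

  list(genes = tx, gene_table = gene_table, counts = counts,
       species = species,
       gene_truth = data.table::data.table(gene_id = gene_id,
                                           effect = effect,
                                           coupled = coupled,
                                           direction = direction),
       te_type_reads = type_reads, total_exonic_reads = total_exonic)
}

#' Simulate a complete two-species cohort
#'
#' Convenience wrapper running genome, TE, ChIP and expression simulation in
#' sequence under one configuration.
#'
#' @param cfg a [sim_config()]
#' @return a list with elements `cfg`, `gp`, `tes`, `frags`, `expr`
#' @export
simulate_cohort <- function(cfg) {
  gp <- simulate_genome_pair(cfg)
  tes <- simulate_te_annotations(cfg, gp)
  frags <- simulate_chip_fragments(cfg, gp, tes)
  expr <- simulate_expression(cfg, gp, tes)
  list(cfg = cfg, gp = gp, tes = tes, frags = frags, expr = expr)
}
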