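#' Write a simulated cohort to disk in standard formats
#'
#' Genomes as FASTA, chains in UCSC chain format, per-individual ChIP and
#' Input fragments as BED3, TE tables as 8-column TSV, ground truth and
#' expression counts as TSV.
#'
#' @param cohort output of [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(cohort$gp$genome_a,
                              file.path(dir, "genomeA.fa"))
  Biostrings::writeXStringSet(cohort$gp$genome_b,
                              file.path(dir, "genomeB.fa"))
  write_chain(cohort$gp$chain_ab, file.path(dir, "A_to_B.chain"))
  write_chain(cohort$gp$chain_ba, file.path(dir, "B_to_A.chain"))
  write_te_table(cohort$tes$rmsk_a, file.path(dir, "rmskA.tsv"))
  write_te_table(cohort$tes$rmsk_b, file.path(dir, "rmskB.tsv"))
  data.table::fwrite(cohort$tes$truth, file.path(dir, "truth_te.tsv"),
                     sep = "\t")
  for (ind in names(cohort$frags$chip)) {
    data.table::fwrite(cohort$frags$chip[[ind]],
                       file.path(dir, sprintf("%s_chip.bed", ind)),
                       sep = "\t", col.names = FALSE)
    data.table::fwrite(cohort$frags$input[[ind]],
                       file.path(dir, sprintf("%s_input.bed", ind)),
                       sep = "\t", col.names = FALSE)
  }
  data.table::fwrite(cohort$expr$genes, file.path(dir, "transcripts.tsv"),
                     sep = "\t")
  data.table::fwrite(
    data.table::as.data.table(cohort$expr$counts, keep.rownames = "gene_id"),
    file.path(dir, "gene_counts.tsv"), sep = "\t")
  data.table::fwrite(cohort$expr$gene_truth, file.path(dir, "truth_gene.tsv"),
                     sep = "\t")
  data.table::fwrite(cohort$expr$te_type_reads,
                     file.path(dir, "te_type_reads.tsv"), sep = "\t")
  invisible(dir)
}

#' Read BED3 fragment intervals
#'
#' @param path BED file (0-based half-open, at least 3 columns)
#' @return data.table with `chrom`, `start`, `end`
#' @export
read_fragments <- function(path) {
  dt <- data.table::fread(path, header = FALSE, select = 1:3,
                          col.names = c("chrom", "start", "end"))
  .assert(all(dt$start >= 0 & dt$start < dt$end),
          "invalid fragment intervals in %s", path)
  dt
}
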