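#' Select the single TSS for a gene
#'
#' One TSS is assigned per gene using the transcription start of the 5'-most
#' transcript for sense-strand genes and of the 3'-most transcript for
#' antisense-strand genes, i.e. the minimum `txStart` on `+` and the maximum
#' `txStart` on `-`.
#'
#' @param tx_starts numeric vector of transcript start coordinates (0-based)
#' @param strand `"+"` or `"-"`
#' @return the selected TSS coordinate
#' @export
select_tss <- function(tx_starts, strand) {
  .assert(length(tx_starts) >= 1, "gene has no transcripts")
  .assert(strand %in% c("+", "-"), "strand must be '+' or '-'")
  if (strand == "+") min(tx_starts) else max(tx_starts)
}

#' Upstream window of a TSS
#'
#' Returns the `size`-bp window immediately upstream of the TSS, excluding
#' the TSS base itself and clipped to the chromosome:
#' `[max(0, tss - size), tss)` on the plus strand and
#' `[tss, min(chrom_len, tss + size))` on the minus strand.
#'
#' @param tss TSS coordinate (0-based)
#' @param strand `"+"` or `"-"`
#' @param size window size in bp (the analyses use 1, 10, 20 and 40 kb)
#' @param chrom_len chromosome length for clipping
#' @param chrom chromosome name for the returned interval
#' @return a length-1 `GRanges`
#' @export
upstream_window <- function(tss, strand, size, chrom_len, chrom = "chr1") {
  .assert(size > 0, "window size must be positive")
  .assert(tss >= 0 && tss <= chrom_len, "tss outside chromosome")
  if (strand == "+") {
    s <- max(0, tss - size); e <- tss
  } else {
    s <- tss; e <- min(chrom_len, tss + size)
  }
  if (e <= s) return(GenomicRanges::GRanges())
  gi(chrom, s, e, strand = strand)
}

## vectorized upstream windows; drops empty (fully clipped) windows and
## returns the surviving gene indices
.upstream_windows <- function(tss, strand, size, lens, chrom) {
  s <- ifelse(strand == "+", pmax(0, tss - size), tss)
  e <- ifelse(strand == "+", tss, pmin(lens, tss + size))
  keep <- which(e > s)
  list(gr = gi(chrom[keep], s[keep], e[keep], strand[keep]), idx = keep)
}

#' Read a gene transcript table
#'
#' Expects a TSV with columns `gene_id`, `chrom`, `tx_start`, `tx_end`,
#' `strand` (0-based half-open transcript spans, one row per transcript) and
#' collapses it to one row per gene with the selected TSS.
#'
#' @param path TSV path
#' @return a data.table with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `tss`, `tx_start`, `tx_end`
#' @export
read_gene_table <- function(path) {
  tx <- data.table::fread(path)
  need <- c("gene_id", "chrom", "tx_start", "tx_end", "strand")
  .assert(all(need %in% names(tx)), "gene table must have columns %s",
          paste(need, collapse = ", "))
  .assert(all(tx$tx_start < tx$tx_end), "transcripts must have tx_start < tx_end")
  tx[, list(chrom = chrom[1], strand = strand[1],
            tss = select_tss(tx_start, strand[1]),
            tx_start = min(tx_start), tx_end = max(tx_end)),
     by = "gene_id"]
}
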