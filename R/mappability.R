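#' k-mer mappability track
#'
#' The mappability of a base is `1 / n`, where `n` is the number of exact
#' occurrences in the genome (both strands) of the k-mer starting at that
#' base. Unique k-mers score 1; a k-mer present twice scores 0.5. The last
#' `k - 1` bases of each chromosome inherit the score of the final full
#' k-mer start, so every base carries a value.
#'
#' Occurrences are counted by exact string matching; a k-mer that equals its
#' own reverse complement is counted on both strands.
#'
#' @param genome a `DNAStringSet` (or named character vector of sequences)
#' @param k k-mer length in bp (default 50)
#' @return an object of class `mappability_track`: a list with `k` and
#'   `score`, a per-chromosome list of numeric [S4Vectors::Rle] vectors
#' @export
kmer_mappability <- function(genome, k = 50L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  .assert(is(genome, "DNAStringSet"), "genome must be a DNAStringSet")
  .assert(length(genome) > 0, "genome is empty")
  .assert(k >= 1, "k must be >= 1")
  lens <- Biostrings::width(genome)
  .assert(any(lens >= k), "k = %d exceeds every chromosome length", k)
  chroms <- names(genome)
  if (is.null(chroms)) chroms <- paste0("chr", seq_along(genome))
  kmers_by_chrom <- lapply(seq_along(genome), function(i) {
    L <- lens[i]
    if (L < k) return(character(0))
    s <- as.character(genome[[i]])
    substring(s, 1:(L - k + 1L), k:L)
  })
  all_k <- unlist(kmers_by_chrom, use.names = FALSE)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(all_k)))
  tab <- data.table::data.table(kmer = all_k)[, list(n = .N), by = "kmer"]
  fwd_n <- tab$n[match(all_k, tab$kmer)]
  rev_n <- tab$n[match(rc, tab$kmer)]
  rev_n[is.na(rev_n)] <- 0L
  score_all <- 1 / (fwd_n + rev_n)
  offs <- cumsum(c(0L, vapply(kmers_by_chrom, length, integer(1))))
  score <- lapply(seq_along(genome), function(i) {
    nk <- length(kmers_by_chrom[[i]])
    if (nk == 0L) return(S4Vectors::Rle(numeric(0)))
    v <- score_all[(offs[i] + 1L):(offs[i] + nk)]
    ## trailing k-1 bases inherit the last full k-mer's score
    S4Vectors::Rle(c(v, rep(v[nk], lens[i] - nk)))
  })
  names(score) <- chroms
  structure(list(k = as.integer(k), score = score),
            class = "mappability_track")
}

#' @export
print.mappability_track <- function(x, ...) {
  cat(sprintf("mappability_track k=%d over %d chromosome(s)\n",
              x$k, length(x$score)))
  invisible(x)
}

#' Mean mappability over an interval
#'
#' Arithmetic mean of per-base mappability scores over `[start, end)`.
#' Orthologous regions are retained only when this mean exceeds 0.8 in each
#' species.
#'
#' @param iv a length-1 `GRanges`
#' @param track a `mappability_track` from [kmer_mappability()]
#' @return the mean score, a number in (0, 1]
#' @export
mean_mappability <- function(iv, track) {
  .assert(is(track, "mappability_track"), "track must be a mappability_track")
  .assert(length(iv) == 1L, "mean_mappability expects a single interval")
  chrom <- as.character(GenomeInfoDb::seqnames(iv))
  v <- track$score[[chrom]]
  .assert(!is.null(v), "chromosome %s absent from mappability track", chrom)
  s <- .start0(iv); e <- .end0(iv)
  .assert(s >= 0 && e <= length(v) && e > s,
          "interval %s:%d-%d outside mappability track bounds", chrom, s, e)
  mean(v[(s + 1L):e])
}

## Vectorized mean mappability for same-length interval vectors.
.mean_mappability_many <- function(chrom, start0, end0, track) {
  vapply(seq_along(chrom), function(i) {
    v <- track$score[[chrom[i]]]
    if (is.null(v)) return(NA_real_)
    e <- min(end0[i], length(v)); s <- max(0L, start0[i])
    if (e <= s) return(NA_real_)
    mean(v[(s + 1L):e])
  }, numeric(1))
}
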