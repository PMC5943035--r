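#' Call broad H3K9me3 domains with a windowed Poisson model
#'
#' A simplified broad-domain caller: the genome is tiled in fixed windows;
#' the expected ChIP count in a window is the larger of the depth-scaled
#' Input count and the genome-wide ChIP mean per window; an upper-tail
#' Poisson p-value is computed per window and adjusted by
#' Benjamini-Hochberg; significant windows separated by at most `gap` bp
#' are merged into broad peaks. The lenient default `q_max = 0.1` mirrors
#' broad-mark calling practice, where stringent thresholds fragment
#' megabase-scale domains.
#'
#' Fragments are assigned to windows by their midpoints so each fragment
#' contributes exactly once.
#'
#' @param chip data.table of ChIP fragments (`chrom`, `start`, `end`)
#' @param input data.table of Input fragments, same layout
#' @param chrom_lens named vector of chromosome lengths
#' @param window window size in bp (default 1000)
#' @param gap maximum distance between significant windows merged into one
#'   peak (default 3000)
#' @param q_max BH-adjusted significance threshold (default 0.1)
#' @return a `GRanges` of peaks with metadata columns `qvalue` (minimum
#'   window q inside the peak) and `enrichment` (total ChIP over total
#'   expected)
#' @export
call_broad_peaks <- function(chip, input, chrom_lens, window = 1000L,
                             gap = 3000L, q_max = 0.1) {
  .assert(nrow(chip) > 0 && nrow(input) > 0,
          "ChIP and Input fragment sets must be nonempty")
  .assert(window >= 1, "window must be >= 1")
  wins <- GenomicRanges::tileGenome(chrom_lens, tilewidth = window,
                                    cut.last.tile.in.chrom = TRUE)
  mid_gr <- function(fr) {
    m <- (fr$start + fr$end) %/% 2L
    gi(fr$chrom, m, m + 1L)
  }
  n_chip <- GenomicRanges::countOverlaps(wins, mid_gr(chip))
  n_input <- GenomicRanges::countOverlaps(wins, mid_gr(input))
  scale <- nrow(chip) / nrow(input)
  lambda <- pmax(n_input * scale, mean(n_chip))
  p <- ppois(n_chip - 1L, lambda, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  sig <- q <= q_max
  if (!any(sig)) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$qvalue <- numeric(0)
    S4Vectors::mcols(out)$enrichment <- numeric(0)
    return(out)
  }
  peaks <- GenomicRanges::reduce(wins[sig], min.gapwidth = gap + 1L)
  ov <- GenomicRanges::findOverlaps(peaks, wins[sig])
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  qs <- q[sig]; cs <- n_chip[sig]; ls <- lambda[sig]
  S4Vectors::mcols(peaks)$qvalue <-
    as.numeric(tapply(qs[sh], qh, min)[as.character(seq_along(peaks))])
  S4Vectors::mcols(peaks)$enrichment <-
    as.numeric(tapply(cs[sh], qh, sum)[as.character(seq_along(peaks))]) /
    pmax(1e-9, as.numeric(tapply(ls[sh], qh, sum)[as.character(seq_along(peaks))]))
  peaks
}
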