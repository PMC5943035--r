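## Orthologous TE construction: lift one species' instances to the other,
## demand a same-name annotation under the lifted span, lift back, repeat
## from the other species, and intersect the two candidate sets.

## One seeded direction: lift src instances into dst, match same-name dst
## instances covering >= min_bp_overlap of the lifted span (largest overlap
## wins, then smallest start), then require the lifted span lifts back.
## Returns data.table(src_idx, dst_idx, back_chrom/start/end in src coords).
.seed_direction <- function(src, dst, chain_fwd, chain_rev,
                            min_match, min_bp_overlap) {
  lifted <- .lift_many(src$chrom, src$start, src$end, chain_fwd, min_match)
  ok <- which(lifted$ok)
  if (!length(ok))
    return(data.table::data.table(src_idx = integer(0), dst_idx = integer(0),
                                  back_chrom = character(0),
                                  back_start = integer(0),
                                  back_end = integer(0)))
  lg <- gi(lifted$t_chrom[ok], lifted$t_start[ok], lifted$t_end[ok])
  dg <- .te_gr(dst)
  ov <- GenomicRanges::findOverlaps(lg, dg)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  same <- src$name[ok][q] == dst$name[s]
  q <- q[same]; s <- s[same]
  if (!length(q)) return(data.table::data.table(
    src_idx = integer(0), dst_idx = integer(0), back_chrom = character(0),
    back_start = integer(0), back_end = integer(0)))
  ow <- IRanges::width(IRanges::pintersect(IRanges::ranges(lg)[q],
                                           IRanges::ranges(dg)[s]))
  pass <- ow >= min_bp_overlap * IRanges::width(lg)[q]
  q <- q[pass]; s <- s[pass]; ow <- ow[pass]
  if (!length(q)) return(data.table::data.table(
    src_idx = integer(0), dst_idx = integer(0), back_chrom = character(0),
    back_start = integer(0), back_end = integer(0)))
  cand <- data.table::data.table(q = q, s = s, ow = ow,
                                 dstart = GenomicRanges::start(dg)[s])
  ## ties: largest base overlap, then smallest start; deterministic
  data.table::setorderv(cand, c("q", "ow", "dstart"), c(1L, -1L, 1L))
  cand <- cand[!duplicated(cand$q)]
  back <- .lift_many(lifted$t_chrom[ok][cand$q], lifted$t_start[ok][cand$q],
                     lifted$t_end[ok][cand$q], chain_rev, min_match)
  kept <- which(back$ok)
  data.table::data.table(src_idx = ok[cand$q[kept]],
                         dst_idx = cand$s[kept],
                         back_chrom = back$t_chrom[kept],
                         back_start = back$t_start[kept],
                         back_end = back$t_end[kept])
}

#' Build the orthologous TE set by reciprocal lifting and name matching
#'
#' Four-step reciprocal procedure: (1) lift species-A instances to genome B
#' at `min_match`; (2) keep those whose lifted span is covered at least
#' `min_bp_overlap` by a B instance with the identical type name (largest
#' overlap on ties); (3) lift the retained spans back to genome A and keep
#' those that return; (4) repeat seeded from species B; (5) intersect the
#' two candidate pair sets, requiring reciprocal overlap of at least
#' `min_bp_overlap` of the shorter span in genome-A coordinates.
#'
#' @param rmsk_a,rmsk_b TE tables (see [read_te_table()])
#' @param chain_ab,chain_ba chain sets A->B and B->A
#' @param min_match minimum lift match fraction (default 0.7)
#' @param min_bp_overlap minimum base-pair overlap fraction (default 0.5)
#' @return a data.table of orthologous pairs: indices and coordinates of
#'   the A and B instances plus the shared `name`; TE length and milliDiv
#'   are reported from the A instance
#' @export
orthologous_te_set <- function(rmsk_a, rmsk_b, chain_ab, chain_ba,
                               min_match = 0.7, min_bp_overlap = 0.5) {
  ab <- .seed_direction(rmsk_a, rmsk_b, chain_ab, chain_ba,
                        min_match, min_bp_overlap)
  ba <- .seed_direction(rmsk_b, rmsk_a, chain_ba, chain_ab,
                        min_match, min_bp_overlap)
  if (!nrow(ab) || !nrow(ba)) {
    return(data.table::data.table(
      idx_a = integer(0), idx_b = integer(0), name = character(0),
      chrom_a = character(0), start_a = integer(0), end_a = integer(0),
      chrom_b = character(0), start_b = integer(0), end_b = integer(0),
      milli_div = numeric(0), te_class = character(0), family = character(0)))
  }
  pairs_ab <- data.table::data.table(idx_a = ab$src_idx, idx_b = ab$dst_idx)
  ## B-seeded pairs carry their lifted genome-A span for the stage-5 check
  pairs_ba <- data.table::data.table(idx_a = ba$dst_idx, idx_b = ba$src_idx,
                                     a_chrom = ba$back_chrom,
                                     a_start = ba$back_start,
                                     a_end = ba$back_end)
  m <- merge(pairs_ab, pairs_ba, by = c("idx_a", "idx_b"))
  if (!nrow(m)) return(orthologous_te_set(rmsk_a[0], rmsk_b[0],
                                          chain_ab, chain_ba))
  ## reciprocal overlap in A coordinates against the annotated A instance
  a_s <- rmsk_a$start[m$idx_a]; a_e <- rmsk_a$end[m$idx_a]
  ov <- pmax(0L, pmin(a_e, m$a_end) - pmax(a_s, m$a_start))
  shorter <- pmin(a_e - a_s, m$a_end - m$a_start)
  keep <- rmsk_a$chrom[m$idx_a] == m$a_chrom & ov >= min_bp_overlap * shorter
  m <- m[keep]
  data.table::data.table(
    idx_a = m$idx_a, idx_b = m$idx_b, name = rmsk_a$name[m$idx_a],
    chrom_a = rmsk_a$chrom[m$idx_a], start_a = rmsk_a$start[m$idx_a],
    end_a = rmsk_a$end[m$idx_a],
    chrom_b = rmsk_b$chrom[m$idx_b], start_b = rmsk_b$start[m$idx_b],
    end_b = rmsk_b$end[m$idx_b],
    milli_div = rmsk_a$milli_div[m$idx_a],
    te_class = rmsk_a$te_class[m$idx_a],
    family = rmsk_a$family[m$idx_a])
}

#' Partition TE instances by orthology
#'
#' Non-orthologous instances are all instances not in the orthologous set;
#' species-specific instances are the non-orthologous ones whose type name
#' is absent from the other species' table (the pattern of annotations like
#' human-only SVA_E/SVA_F). The sets are disjoint and exhaustive per
#' species.
#'
#' @param rmsk_a,rmsk_b TE tables
#' @param ortho output of [orthologous_te_set()]
#' @return list of data.tables: `orthologous`, `non_orthologous_a`,
#'   `non_orthologous_b`, `species_specific_a`, `species_specific_b`
#' @export
partition_te_sets <- function(rmsk_a, rmsk_b, ortho) {
  non_a <- rmsk_a[!seq_len(nrow(rmsk_a)) %in% ortho$idx_a]
  non_b <- rmsk_b[!seq_len(nrow(rmsk_b)) %in% ortho$idx_b]
  list(orthologous = ortho,
       non_orthologous_a = non_a,
       non_orthologous_b = non_b,
       species_specific_a = non_a[!non_a$name %in% unique(rmsk_b$name)],
       species_specific_b = non_b[!non_b$name %in% unique(rmsk_a$name)])
}
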