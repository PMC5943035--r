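## Interval lifting across chain alignments with liftOver-style minimum-match
## semantics and cross-chain uniqueness.

## Coverage and envelope mapping of many 0-based intervals against ONE chain.
## Returns data.table(idx, covered, t_chrom, t_start, t_end) for intervals
## touching at least one aligned block.
.lift_one_chain <- function(chrom, start0, end0, ch) {
  on_chrom <- which(chrom == ch$s_chrom)
  if (!length(on_chrom)) return(NULL)
  b <- ch$blocks
  ir_iv <- IRanges::IRanges(start0[on_chrom] + 1L, end0[on_chrom])
  ir_bl <- IRanges::IRanges(ch$s_bs + 1L, ch$s_bs + b$size)
  ov <- IRanges::findOverlaps(ir_iv, ir_bl)
  if (!length(ov)) return(NULL)
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  cw <- IRanges::width(IRanges::pintersect(ir_iv[q], ir_bl[s]))
  dt <- data.table::data.table(q = q, s = s, cw = cw)
  agg <- dt[, list(covered = sum(cw), first = min(s), last = max(s)), by = "q"]
  iv0 <- start0[on_chrom][agg$q]
  iv1 <- end0[on_chrom][agg$q] ## exclusive
  f0 <- pmax(iv0, ch$s_bs[agg$first])
  l0 <- pmin(iv1 - 1L, ch$s_bs[agg$last] + b$size[agg$last] - 1L)
  tf <- ch$t_bs[agg$first] + (f0 - ch$s_bs[agg$first])
  tl <- ch$t_bs[agg$last] + (l0 - ch$s_bs[agg$last])
  if (ch$t_strand == "-") {
    tf <- ch$t_size - 1L - tf
    tl <- ch$t_size - 1L - tl
  }
  data.table::data.table(idx = on_chrom[agg$q], covered = agg$covered,
                         t_chrom = ch$t_chrom,
                         t_start = pmin(tf, tl), t_end = pmax(tf, tl) + 1L)
}

## Vectorized lift of 0-based intervals through a chain_set.
## Policy: an interval maps iff EXACTLY ONE chain covers >= min_match of its
## bases; the envelope of the mapped bases under that chain is returned.
## Reasons: no_chain, low_match, nonreciprocal (ambiguous multi-chain), ok.
.lift_many <- function(chrom, start0, end0, chains, min_match = 0.7) {
  chains <- .as_chain_set(chains)
  .assert(min_match > 0 && min_match <= 1, "min_match must be in (0,1]")
  n <- length(chrom)
  out <- data.table::data.table(
    idx = seq_len(n), ok = FALSE, reason = "no_chain",
    t_chrom = NA_character_, t_start = NA_integer_, t_end = NA_integer_)
  if (!n) return(out)
  per <- data.table::rbindlist(
    lapply(chains, function(ch) .lift_one_chain(chrom, start0, end0, ch)),
    idcol = "chain_i")
  if (!nrow(per)) return(out)
  width <- end0 - start0
  per[, "pass" := per$covered >= min_match * width[per$idx]]
  touched <- unique(per$idx)
  out[touched, "reason" := "low_match"]
  passed <- per[per$pass == TRUE]
  if (!nrow(passed)) return(out)
  npass <- passed[, list(k = .N), by = "idx"]
  ambig <- npass$idx[npass$k > 1L]
  out[ambig, "reason" := "nonreciprocal"]
  uniq <- passed[passed$idx %in% npass$idx[npass$k == 1L]]
  if (nrow(uniq)) {
    out[uniq$idx, c("ok", "reason", "t_chrom", "t_start", "t_end") :=
          list(TRUE, "ok", uniq$t_chrom, uniq$t_start, uniq$t_end)]
  }
  out
}

#' Lift an interval to the other genome through alignment chains
#'
#' Implements liftOver-style minimum-match lifting: the interval maps iff at
#' least `min_match` of its bases fall inside aligned blocks of a chain, and
#' exactly one chain attains that coverage (two qualifying chains make the
#' mapping ambiguous and the interval is dropped). The returned interval is
#' the envelope of the mapped bases in target plus-strand coordinates.
#'
#' @param iv a length-1 `GRanges` (see [gi()])
#' @param chains a `chain_set` from [read_chain()] or the simulator
#' @param min_match minimum fraction of source bases inside aligned blocks
#'   (default 0.7, the usual 70 percent sequence-match threshold)
#' @return a length-1 `GRanges` in target coordinates, or `NULL` if the
#'   interval does not lift
#' @export
lift_interval <- function(iv, chains, min_match = 0.7) {
  .assert(length(iv) == 1L, "lift_interval expects a single interval")
  r <- .lift_many(as.character(GenomeInfoDb::seqnames(iv)),
                  .start0(iv), .end0(iv), chains, min_match)
  if (!r$ok[1]) return(NULL)
  gi(r$t_chrom[1], r$t_start[1], r$t_end[1])
}

#' Reciprocally lift an interval and require it maps back onto itself
#'
#' An interval is reciprocally mapped when it lifts to the target genome, the
#' lifted interval lifts back, and the round-trip interval overlaps the
#' original by at least `min_match` of the original's length. This is the
#' filter behind "reciprocally and uniquely mapped" orthologous regions.
#'
#' @inheritParams lift_interval
#' @param chain_fwd chains source -> target
#' @param chain_rev chains target -> source (must invert `chain_fwd` on their
#'   shared blocks)
#' @return a list with elements `ok` (logical), `source` and `target`
#'   (`GRanges` or `NULL`), and `reason` (one of `ok`, `no_chain`,
#'   `low_match_fwd`, `low_match_back`, `nonreciprocal`)
#' @export
reciprocal_lift <- function(iv, chain_fwd, chain_rev, min_match = 0.7) {
  .assert(length(iv) == 1L, "reciprocal_lift expects a single interval")
  r <- .reciprocal_lift_many(as.character(GenomeInfoDb::seqnames(iv)),
                             .start0(iv), .end0(iv),
                             chain_fwd, chain_rev, min_match)
  if (!r$ok[1])
    return(list(ok = FALSE, source = NULL, target = NULL, reason = r$reason[1]))
  list(ok = TRUE, source = iv,
       target = gi(r$t_chrom[1], r$t_start[1], r$t_end[1]), reason = "ok")
}

## Vectorized reciprocal lift; returns data.table(idx, ok, reason, t_*).
.reciprocal_lift_many <- function(chrom, start0, end0,
                                  chain_fwd, chain_rev, min_match = 0.7) {
  fwd <- .lift_many(chrom, start0, end0, chain_fwd, min_match)
  out <- data.table::copy(fwd)
  out[out$reason == "low_match", "reason" := "low_match_fwd"]
  hit <- which(fwd$ok)
  if (!length(hit)) return(out)
  back <- .lift_many(fwd$t_chrom[hit], fwd$t_start[hit], fwd$t_end[hit],
                     chain_rev, min_match)
  fail_back <- hit[!back$ok]
  out[fail_back, c("ok", "reason", "t_chrom", "t_start", "t_end") := list(
    FALSE,
    ifelse(back$reason[!back$ok] == "nonreciprocal",
           "nonreciprocal", "low_match_back"),
    NA_character_, NA_integer_, NA_integer_)]
  ok2 <- hit[back$ok]
  if (!length(ok2)) return(out)
  b2 <- back[back$ok]
  same_chr <- b2$t_chrom == chrom[ok2]
  ov <- pmax(0L, pmin(b2$t_end, end0[ok2]) - pmax(b2$t_start, start0[ok2]))
  bad <- ok2[!(same_chr & ov >= min_match * (end0[ok2] - start0[ok2]))]
  out[bad, c("ok", "reason", "t_chrom", "t_start", "t_end") :=
        list(FALSE, "low_match_back", NA_character_, NA_integer_, NA_integer_)]
  out
}
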