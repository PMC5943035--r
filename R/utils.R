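#' @importFrom methods is
#' @importFrom stats median quantile rbinom rgamma rnbinom rnorm rpois runif
#'   sd var cor complete.cases p.adjust pchisq pnorm ppois setNames rgeom
#'   rlnorm
#' @importFrom utils head tail
NULL

## data.table syntax is used throughout via ::, mark the namespace aware
.datatable.aware <- TRUE

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) .stopf(fmt, ...)
  invisible(TRUE)
}

.is_prob <- function(x) is.numeric(x) && all(x >= 0 & x <= 1)

#' Construct a genomic interval
#'
#' Intervals throughout the package are 0-based, half-open `[start, end)`,
#' the convention of BED and chain files. Internally they are stored as
#' `GRanges` (1-based closed), converted at the boundary.
#'
#' @param chrom chromosome name
#' @param start 0-based inclusive start
#' @param end exclusive end; must satisfy `start < end`
#' @param strand `"+"`, `"-"` or `"*"`
#' @return a `GRanges` of length `length(start)`
#' @export
gi <- function(chrom, start, end, strand = "*") {
  .assert(all(nzchar(chrom)), "chrom must be nonempty")
  .assert(all(start >= 0) && all(start < end),
          "invalid interval: need 0 <= start < end")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                         strand = strand)
}

## 0-based starts/exclusive ends of a GRanges
.start0 <- function(gr) GenomicRanges::start(gr) - 1L
.end0 <- function(gr) GenomicRanges::end(gr)

.gr_from_dt <- function(dt, chrom = "chrom", start = "start", end = "end") {
  gi(dt[[chrom]], dt[[start]], dt[[end]])
}
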