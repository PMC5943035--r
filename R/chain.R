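#' Pairwise alignment chains
#'
#' A `chain` is one gapped alignment between a source and a target genome in
#' the UCSC chain format: a scored header plus an ordered list of aligned
#' blocks `(size, ds, dt)` where `ds`/`dt` are the gap lengths following the
#' block on the source/target side. A `chain_set` is a list of chains, the
#' unit that [lift_interval()] consumes.
#'
#' Coordinates are 0-based half-open. Target coordinates of minus-strand
#' chains are stored in reverse-strand space exactly as in the file format
#' and converted to plus-strand coordinates during lifting.
#'
#' @param score alignment score
#' @param s_chrom,s_size,s_start,s_end source chromosome, its length, and the
#'   aligned span
#' @param t_chrom,t_size,t_strand,t_start,t_end same for the target genome
#' @param blocks data.frame with columns `size`, `ds`, `dt`; the final row
#'   must have `ds == dt == 0`
#' @param id chain identifier
#' @return an object of class `chain`
#' @export
chain <- function(score, s_chrom, s_size, s_start, s_end,
                  t_chrom, t_size, t_strand, t_start, t_end,
                  blocks, id = 1L) {
  .assert(all(blocks$size > 0), "chain %s: block sizes must be positive", id)
  n <- nrow(blocks)
  .assert(blocks$ds[n] == 0 && blocks$dt[n] == 0,
          "chain %s: final block must have zero trailing gaps", id)
  s_span <- sum(blocks$size) + sum(blocks$ds)
  t_span <- sum(blocks$size) + sum(blocks$dt)
  .assert(s_span == s_end - s_start,
          "chain %s: source blocks span %d but header declares %d",
          id, s_span, s_end - s_start)
  .assert(t_span == t_end - t_start,
          "chain %s: target blocks span %d but header declares %d",
          id, t_span, t_end - t_start)
  ## absolute block starts, precomputed for lifting
  s_bs <- s_start + cumsum(c(0, (blocks$size + blocks$ds)[-n]))
  t_bs <- t_start + cumsum(c(0, (blocks$size + blocks$dt)[-n]))
  structure(list(score = score,
                 s_chrom = s_chrom, s_size = s_size,
                 s_start = s_start, s_end = s_end,
                 t_chrom = t_chrom, t_size = t_size, t_strand = t_strand,
                 t_start = t_start, t_end = t_end,
                 blocks = blocks, s_bs = s_bs, t_bs = t_bs, id = id),
            class = "chain")
}

#' @export
print.chain <- function(x, ...) {
  cat(sprintf("chain %s score=%g %s:%d-%d -> %s:%d-%d (%s) %d blocks\n",
              x$id, x$score, x$s_chrom, x$s_start, x$s_end,
              x$t_chrom, x$t_start, x$t_end, x$t_strand, nrow(x$blocks)))
  invisible(x)
}

.as_chain_set <- function(x) {
  if (is(x, "chain")) x <- list(x)
  .assert(all(vapply(x, function(ch) is(ch, "chain"), logical(1))),
          "expected a chain or list of chains")
  structure(x, class = "chain_set")
}

#' Read a UCSC chain file
#'
#' @param path path to a chain-format file
#' @return a `chain_set` (list of [chain()] objects)
#' @export
read_chain <- function(path) {
  .assert(file.exists(path), "chain file not found: %s", path)
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1L; next }
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (f[1] != "chain" || length(f) < 12)
      .stopf("malformed chain header at line %d: %s", i, ln)
    hdr <- f
    blocks <- list()
    i <- i + 1L
    repeat {
      if (i > length(lines)) .stopf("truncated chain ending at line %d", i - 1L)
      bl <- trimws(lines[i])
      if (!nzchar(bl)) .stopf("empty line inside chain block list at line %d", i)
      bf <- suppressWarnings(as.numeric(strsplit(bl, "[ \t]+")[[1]]))
      if (anyNA(bf)) .stopf("malformed block line at line %d: %s", i, bl)
      if (length(bf) == 1) { blocks[[length(blocks) + 1L]] <- c(bf, 0, 0); i <- i + 1L; break }
      if (length(bf) != 3) .stopf("block line at line %d must have 1 or 3 fields", i)
      blocks[[length(blocks) + 1L]] <- bf
      i <- i + 1L
    }
    bm <- do.call(rbind, blocks)
    bdf <- data.frame(size = as.integer(bm[, 1]), ds = as.integer(bm[, 2]),
                      dt = as.integer(bm[, 3]))
    ch <- tryCatch(
      chain(score = as.numeric(hdr[2]),
            s_chrom = hdr[3], s_size = as.integer(hdr[4]),
            s_start = as.integer(hdr[6]), s_end = as.integer(hdr[7]),
            t_chrom = hdr[8], t_size = as.integer(hdr[9]),
            t_strand = hdr[10],
            t_start = as.integer(hdr[11]), t_end = as.integer(hdr[12]),
            blocks = bdf,
            id = if (length(hdr) >= 13) hdr[13] else as.character(length(chains) + 1L)),
      error = function(e) .stopf("chain ending at line %d: %s", i - 1L, conditionMessage(e)))
    .assert(hdr[5] == "+", "source strand must be '+' (line with chain id %s)", ch$id)
    chains[[length(chains) + 1L]] <- ch
  }
  .as_chain_set(chains)
}

#' Write a chain_set to a UCSC chain file
#'
#' @param chains a `chain_set` or single `chain`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_chain <- function(chains, path) {
  chains <- .as_chain_set(chains)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(sprintf("chain %s %s %d + %d %d %s %d %s %d %d %s",
                       format(ch$score, scientific = FALSE, trim = TRUE),
                       ch$s_chrom, ch$s_size, ch$s_start, ch$s_end,
                       ch$t_chrom, ch$t_size, ch$t_strand,
                       ch$t_start, ch$t_end, ch$id), con)
    b <- ch$blocks
    n <- nrow(b)
    if (n > 1)
      writeLines(sprintf("%d\t%d\t%d", b$size[-n], b$ds[-n], b$dt[-n]), con)
    writeLines(c(sprintf("%d", b$size[n]), ""), con)
  }
  invisible(path)
}

#' Invert a plus-strand chain set
#'
#' Swaps source and target so that a chain describing A->B describes B->A.
#' Only plus-strand chains can be inverted this way.
#'
#' @param chains a `chain_set`
#' @return the inverted `chain_set`
#' @export
invert_chain <- function(chains) {
  chains <- .as_chain_set(chains)
  .as_chain_set(lapply(chains, function(ch) {
    .assert(ch$t_strand == "+", "only plus-strand chains can be inverted")
    chain(score = ch$score,
          s_chrom = ch$t_chrom, s_size = ch$t_size,
          s_start = ch$t_start, s_end = ch$t_end,
          t_chrom = ch$s_chrom, t_size = ch$s_size, t_strand = "+",
          t_start = ch$s_start, t_end = ch$s_end,
          blocks = data.frame(size = ch$blocks$size, ds = ch$blocks$dt,
                              dt = ch$blocks$ds),
          id = ch$id)
  }))
}
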