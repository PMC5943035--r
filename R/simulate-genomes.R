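## Ancestor-based genome pair simulation. One ancestral sequence per
## chromosome; each descendant accumulates substitutions and indels
## independently. Because both descendants carry an exact coordinate map to
## the ancestor, the A<->B chains are computed by composition and are exact
## inverses of one another by construction.

.BASES <- c("A", "C", "G", "T")

## Apply substitutions + indels to one ancestral chromosome (character
## vector). Returns the descendant sequence, an ancestor->descendant segment
## map (0-based: anc_start, anc_end, desc_start), and the indel event log.
.evolve_chrom <- function(anc, substitution_rate, indel_rate, mean_indel_len) {
  L <- length(anc)
  seq <- anc
  nsub <- rbinom(1L, L, substitution_rate)
  if (nsub > 0) {
    at <- sample.int(L, nsub)
    ## substitute with one of the three other bases
    shift <- sample.int(3L, nsub, replace = TRUE)
    seq[at] <- .BASES[((match(seq[at], .BASES) - 1L + shift) %% 4L) + 1L]
  }
  n_ev <- rpois(1L, L * indel_rate)
  events <- NULL
  if (n_ev > 0) {
    pos <- sort(sample.int(L, min(n_ev, L)))
    type <- sample(c("del", "ins"), length(pos), replace = TRUE)
    len <- 1L + rgeom(length(pos), prob = min(1, 1 / mean_indel_len))
    events <- data.table::data.table(pos = pos - 1L, type = type, len = len)
  }
  segs <- list()
  pieces <- list()
  cur_anc <- 0L; cur_desc <- 0L
  kept <- logical(0)
  if (!is.null(events)) {
    for (i in seq_len(nrow(events))) {
      p <- events$pos[i]
      if (p < cur_anc || p >= L) { kept <- c(kept, FALSE); next }
      kept <- c(kept, TRUE)
      if (p > cur_anc) {
        segs[[length(segs) + 1L]] <- c(cur_anc, p, cur_desc)
        pieces[[length(pieces) + 1L]] <- seq[(cur_anc + 1L):p]
        cur_desc <- cur_desc + (p - cur_anc)
        cur_anc <- p
      }
      l <- events$len[i]
      if (events$type[i] == "del") {
        cur_anc <- min(L, cur_anc + l)
      } else {
        ins <- sample(.BASES, l, replace = TRUE)
        pieces[[length(pieces) + 1L]] <- ins
        cur_desc <- cur_desc + l
      }
    }
    events <- events[kept]
  }
  if (cur_anc < L) {
    segs[[length(segs) + 1L]] <- c(cur_anc, L, cur_desc)
    pieces[[length(pieces) + 1L]] <- seq[(cur_anc + 1L):L]
  }
  segmat <- do.call(rbind, segs)
  map <- data.table::data.table(anc_start = segmat[, 1], anc_end = segmat[, 2],
                                desc_start = segmat[, 3])
  list(seq = unlist(pieces, use.names = FALSE), map = map,
       events = if (is.null(events)) {
         data.table::data.table(pos = integer(0), type = character(0),
                                len = integer(0))
       } else events)
}

## Project 0-based ancestor intervals through a segment map. Returns the
## envelope of mapped bases plus the number of mapped bases.
.project_map <- function(map, start0, end0) {
  ir_iv <- IRanges::IRanges(start0 + 1L, end0)
  ir_seg <- IRanges::IRanges(map$anc_start + 1L, map$anc_end)
  ov <- IRanges::findOverlaps(ir_iv, ir_seg)
  n <- length(start0)
  out <- data.table::data.table(start = NA_integer_, end = NA_integer_,
                                covered = 0L)[rep(1L, n)]
  if (!length(ov)) return(out)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  cw <- IRanges::width(IRanges::pintersect(ir_iv[q], ir_seg[s]))
  dt <- data.table::data.table(q = q, s = s, cw = cw)
  agg <- dt[, list(covered = sum(cw), first = min(s), last = max(s)), by = "q"]
  f0 <- pmax(start0[agg$q], map$anc_start[agg$first])
  l0 <- pmin(end0[agg$q] - 1L, map$anc_end[agg$last] - 1L)
  ds <- map$desc_start[agg$first] + (f0 - map$anc_start[agg$first])
  de <- map$desc_start[agg$last] + (l0 - map$anc_start[agg$last]) + 1L
  out[agg$q, c("start", "end", "covered") :=
        list(as.integer(ds), as.integer(de), agg$covered)]
  out
}

## Compose two ancestor->descendant maps into a chain descA -> descB.
.compose_chain <- function(chrom, chrom_len_a, chrom_len_b, map_a, map_b,
                           id) {
  ir_a <- IRanges::IRanges(map_a$anc_start + 1L, map_a$anc_end)
  ir_b <- IRanges::IRanges(map_b$anc_start + 1L, map_b$anc_end)
  ov <- IRanges::findOverlaps(ir_a, ir_b)
  ia <- S4Vectors::queryHits(ov); ib <- S4Vectors::subjectHits(ov)
  o1 <- pmax(map_a$anc_start[ia], map_b$anc_start[ib])
  o2 <- pmin(map_a$anc_end[ia], map_b$anc_end[ib])
  a1 <- map_a$desc_start[ia] + (o1 - map_a$anc_start[ia])
  b1 <- map_b$desc_start[ib] + (o1 - map_b$anc_start[ib])
  sz <- o2 - o1
  ord <- order(a1)
  a1 <- a1[ord]; b1 <- b1[ord]; sz <- sz[ord]
  ## merge blocks contiguous in both genomes
  if (length(sz) > 1) {
    keep <- c(TRUE, !(a1[-1] == (a1 + sz)[-length(a1)] &
                        b1[-1] == (b1 + sz)[-length(b1)]))
    grp <- cumsum(keep)
    a1m <- a1[keep]; b1m <- b1[keep]
    szm <- as.integer(tapply(sz, grp, sum))
    a1 <- a1m; b1 <- b1m; sz <- szm
  }
  n <- length(sz)
  ds <- c(a1[-1] - (a1 + sz)[-n], 0L)
  dt <- c(b1[-1] - (b1 + sz)[-n], 0L)
  chain(score = sum(sz),
        s_chrom = chrom, s_size = chrom_len_a,
        s_start = a1[1], s_end = a1[n] + sz[n],
        t_chrom = chrom, t_size = chrom_len_b, t_strand = "+",
        t_start = b1[1], t_end = b1[n] + sz[n],
        blocks = data.frame(size = sz, ds = as.integer(ds),
                            dt = as.integer(dt)),
        id = id)
}

#' Simulate a pair of genomes descended from a common ancestor
#'
#' Draws a random ancestral genome, evolves two descendants independently by
#' substitutions and indels, and returns both genomes together with the
#' exact A->B and B->A alignment chains implied by the true base-level
#' correspondence. `chain_ba` is the inversion of `chain_ab`.
#'
#' @param cfg a [sim_config()]
#' @return a list with `genome_a`, `genome_b` (`DNAStringSet`), `chain_ab`,
#'   `chain_ba` (`chain_set`), per-lineage ancestor coordinate maps `map_a`,
#'   `map_b`, and `event_log` (realized indels per lineage/chromosome)
#' @export
simulate_genome_pair <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  seq_a <- seq_b <- vector("list", cfg$n_chrom)
  map_a <- map_b <- vector("list", cfg$n_chrom)
  chains <- vector("list", cfg$n_chrom)
  logs <- list()
  for (i in seq_len(cfg$n_chrom)) {
    anc <- sample(.BASES, cfg$chrom_len, replace = TRUE)
    da <- .evolve_chrom(anc, cfg$substitution_rate, cfg$indel_rate,
                        cfg$mean_indel_len)
    db <- .evolve_chrom(anc, cfg$substitution_rate, cfg$indel_rate,
                        cfg$mean_indel_len)
    seq_a[[i]] <- paste(da$seq, collapse = "")
    seq_b[[i]] <- paste(db$seq, collapse = "")
    map_a[[i]] <- da$map
    map_b[[i]] <- db$map
    chains[[i]] <- .compose_chain(chroms[i], nchar(seq_a[[i]]),
                                  nchar(seq_b[[i]]), da$map, db$map,
                                  id = as.character(i))
    if (nrow(da$events))
      logs[[length(logs) + 1L]] <-
        data.table::data.table(species = "A", chrom = chroms[i], da$events)
    if (nrow(db$events))
      logs[[length(logs) + 1L]] <-
        data.table::data.table(species = "B", chrom = chroms[i], db$events)
  }
  genome_a <- Biostrings::DNAStringSet(unlist(seq_a))
  genome_b <- Biostrings::DNAStringSet(unlist(seq_b))
  names(genome_a) <- names(genome_b) <- chroms
  names(map_a) <- names(map_b) <- chroms
  chain_ab <- .as_chain_set(chains)
  list(genome_a = genome_a, genome_b = genome_b,
       chain_ab = chain_ab, chain_ba = invert_chain(chain_ab),
       map_a = map_a, map_b = map_b,
       event_log = if (length(logs)) data.table::rbindlist(logs) else
         data.table::data.table(species = character(0), chrom = character(0),
                                pos = integer(0), type = character(0),
                                len = integer(0)))
}
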