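# Independent brute-force oracles and fixture builders shared across tests.

# identity chain covering one chromosome of the given length
identity_chain <- function(len = 1000L, chrom = "chr1") {
  chain(score = len, s_chrom = chrom, s_size = len, s_start = 0L,
        s_end = len, t_chrom = chrom, t_size = len, t_strand = "+",
        t_start = 0L, t_end = len,
        blocks = data.frame(size = len, ds = 0L, dt = 0L), id = "id1")
}

# hand-built multi-block chain: blocks with source and target gaps
multi_block_chain <- function(chrom = "chr1", id = "mb1", score = 1000) {
  blocks <- data.frame(size = c(500L, 300L, 700L, 200L),
                       ds = c(100L, 0L, 250L, 0L),
                       dt = c(0L, 400L, 50L, 0L))
  s_span <- sum(blocks$size) + sum(blocks$ds)
  t_span <- sum(blocks$size) + sum(blocks$dt)
  chain(score = score, s_chrom = chrom, s_size = 10000L, s_start = 1000L,
        s_end = 1000L + s_span, t_chrom = "chrT", t_size = 10000L,
        t_strand = "+", t_start = 2000L, t_end = 2000L + t_span,
        blocks = blocks, id = id)
}

# brute-force per-base lift: maps every base of [start0, end0) through each
# chain independently (binary search per base) and applies the same
# best-unique-chain policy as lift_interval, returning the envelope or NULL
brute_force_lift <- function(chrom, start0, end0, chains, min_match) {
  if (inherits(chains, "chain")) chains <- list(chains)
  per_chain <- lapply(chains, function(ch) {
    if (ch$s_chrom != chrom) return(NULL)
    p <- start0:(end0 - 1L)
    bi <- findInterval(p, ch$s_bs)
    ok <- bi >= 1L
    ok[ok] <- p[ok] < ch$s_bs[bi[ok]] + ch$blocks$size[bi[ok]]
    tp <- ch$t_bs[bi[ok]] + (p[ok] - ch$s_bs[bi[ok]])
    if (ch$t_strand == "-") tp <- ch$t_size - 1L - tp
    list(n = sum(ok), chrom = ch$t_chrom, pos = tp)
  })
  per_chain <- Filter(Negate(is.null), per_chain)
  if (!length(per_chain)) return(NULL)
  covered <- vapply(per_chain, function(x) x$n, numeric(1))
  pass <- which(covered >= min_match * (end0 - start0))
  if (length(pass) != 1L) return(NULL)
  ps <- per_chain[[pass]]$pos
  list(chrom = per_chain[[pass]]$chrom, start = min(ps), end = max(ps) + 1L)
}

# step-up FDR adjustment written independently of stats::p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# small cohort used by several module tests (about 5 s to simulate)
small_cohort <- function(seed = 42L, ...) {
  simulate_cohort(sim_config(seed = seed, n_chrom = 2L, chrom_len = 2e5,
                             n_te = 500L,
                             n_individuals_per_species = c(A = 5L, B = 4L),
                             n_genes = 60L, ...))
}

# random DNA as a DNAStringSet
random_genome <- function(lens, seed = 1L) {
  set.seed(seed)
  g <- Biostrings::DNAStringSet(vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)))
  names(g) <- names(lens)
  g
}
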