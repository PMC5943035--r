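## TE annotation simulation: hierarchical class/family/type repertoire,
## partition-based placement on the ancestor (guaranteed non-overlapping),
## projection into each descendant, and ground-truth silencing / orthology
## labels.

## shared type repertoire: type -> (family, class)
.te_repertoire <- function() {
  data.table::data.table(
    name = c("L1PA2", "L1PA4", "L1MB7",
             "AluY", "AluSx", "AluJb", "MIRb",
             "LTR5B", "MER11A", "MLT1A",
             "MER5A", "Tigger1", "Charlie1",
             "SVA_A", "SVA_B", "SVA_C", "SVA_D"),
    family = c("L1", "L1", "L1",
               "Alu", "Alu", "Alu", "MIR",
               "ERVK", "ERVK", "ERVL-MaLR",
               "hAT-Charlie", "TcMar-Tigger", "hAT-Charlie",
               "SVA", "SVA", "SVA", "SVA"),
    te_class = c("LINE", "LINE", "LINE",
                 "SINE", "SINE", "SINE", "SINE",
                 "LTR", "LTR", "LTR",
                 "DNA", "DNA", "DNA",
                 "SVA", "SVA", "SVA", "SVA"))
}

## species-private type names (absent from the other species' table),
## emulating e.g. SVA_E/SVA_F annotated in human only
.te_private <- function() {
  list(
    A = data.table::data.table(
      name = c("L1HS", "AluYa5", "LTR5_Hs", "MER75_Hs", "SVA_E", "SVA_F"),
      family = c("L1", "Alu", "ERVK", "piggyBac", "SVA", "SVA"),
      te_class = c("LINE", "SINE", "LTR", "DNA", "SVA", "SVA")),
    B = data.table::data.table(
      name = c("L1Pt", "AluYpt", "PtERV1", "MER75_Pt", "SVA_Pt"),
      family = c("L1", "Alu", "ERV1", "piggyBac", "SVA"),
      te_class = c("LINE", "SINE", "LTR", "DNA", "SVA")))
}

.te_len_params <- c(LINE = 300, SINE = 120, LTR = 220, DNA = 150, SVA = 450)
.te_len_sd <- c(LINE = 90, SINE = 30, LTR = 70, DNA = 45, SVA = 140)
.te_mdiv_mean <- c(LINE = 150, SINE = 120, LTR = 130, DNA = 180, SVA = 40)
.te_mdiv_sd <- c(LINE = 80, SINE = 60, LTR = 70, DNA = 80, SVA = 25)

.rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) && tries < 50L) {
    x[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- which(x < lo | x > hi)
    tries <- tries + 1L
  }
  pmin(hi, pmax(lo, x))
}

## Place n non-overlapping spans of the given lengths on [0, chrom_len):
## random gaps partition the free space, so placement always succeeds when
## the lengths fit. A minimum inter-TE gap keeps neighbouring instances
## resolvable as distinct chromatin domains.
.place_spans <- function(lengths, chrom_len, min_gap = 150L) {
  n <- length(lengths)
  if (!n) return(integer(0))
  free <- chrom_len - sum(lengths) - n * min_gap
  if (free < 0) { min_gap <- 0L; free <- chrom_len - sum(lengths) }
  .assert(free >= 0, "TE placements exceed chromosome length")
  g <- rgamma(n + 1L, shape = 1)
  gaps <- min_gap + floor(free * g / sum(g))
  starts <- cumsum(c(0, lengths)) [seq_len(n)] + cumsum(gaps[seq_len(n)])
  as.integer(starts)
}

#' Simulate TE annotation tables for both species with ground truth
#'
#' Places a hierarchical TE annotation (class/family/type) on the ancestral
#' genome, projects instances into each descendant through the true
#' coordinate maps, and assigns ground-truth silencing labels (none /
#' shared / speciesA_only / speciesB_only) and orthology labels
#' (orthologous / non-orthologous / species_specific). Single-genome TEs
#' with species-private type names model annotations like human-only SVA_E
#' and SVA_F. Per-instance milliDiv (substitutions per kb versus the family
#' consensus) is drawn from class-dependent truncated normals, with silenced
#' instances drawn younger (lower milliDiv).
#'
#' @param cfg a [sim_config()]
#' @param gp output of [simulate_genome_pair()]
#' @return a list with `rmsk_a`, `rmsk_b` (data.tables in the 8-column TE
#'   table layout plus a `te_id` key) and `truth` (per-TE labels and
#'   coordinates in both genomes)
#' @export
simulate_te_annotations <- function(cfg, gp) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1000L)
  chroms <- names(gp$genome_a)
  n <- cfg$n_te
  cls <- sample(names(cfg$te_class_weights), n, replace = TRUE,
                prob = cfg$te_class_weights)
  len <- as.integer(round(.rnorm_trunc(n, .te_len_params[cls],
                                       .te_len_sd[cls], 50, 5000)))
  ## chromosome assignment proportional to length budget
  chrom <- sample(chroms, n, replace = TRUE)
  start0 <- integer(n)
  for (ch in chroms) {
    at <- which(chrom == ch)
    if (!length(at)) next
    for (try in 1:20) {
      if (sum(len[at]) <= 0.92 * cfg$chrom_len) break
      ## shed TEs to other chromosomes if overfull (rare at defaults)
      .assert(cfg$n_chrom > 1 && try < 20,
              "could not place TEs within chromosome bounds")
      move <- sample(at, ceiling(length(at) * 0.05))
      chrom[move] <- sample(rep(setdiff(chroms, ch), 2), length(move),
                            replace = TRUE)
      at <- which(chrom == ch)
    }
  }
  for (ch in chroms) {
    at <- which(chrom == ch)
    if (!length(at)) next
    ord <- sample(at) ## random order along the chromosome
    start0[ord] <- .place_spans(len[ord], as.integer(cfg$chrom_len))
  }
  end0 <- start0 + len

  ## orthology labels
  single <- runif(n) < cfg$species_specific_te_rate
  own_sp <- ifelse(runif(n) < 0.5, "A", "B")
  private <- single & (runif(n) < cfg$private_name_fraction)
  orth_label <- ifelse(!single, "orthologous",
                       ifelse(private, "species_specific", "non_orthologous"))

  ## type / family assignment
  rep_shared <- .te_repertoire()
  rep_priv <- .te_private()
  name <- family <- character(n)
  for (cl in .te_classes) {
    at <- which(cls == cl & !private)
    pool <- rep_shared[rep_shared$te_class == cl]
    if (length(at)) {
      pick <- sample.int(nrow(pool), length(at), replace = TRUE)
      name[at] <- pool$name[pick]; family[at] <- pool$family[pick]
    }
    for (sp in c("A", "B")) {
      at <- which(cls == cl & private & own_sp == sp)
      if (!length(at)) next
      pool_p <- rep_priv[[sp]][rep_priv[[sp]]$te_class == cl]
      pick <- sample.int(nrow(pool_p), length(at), replace = TRUE)
      name[at] <- pool_p$name[pick]; family[at] <- pool_p$family[pick]
    }
  }

  ## silencing labels
  prior <- cfg$te_silencing_prior[cls]
  prior[single] <- pmin(1, prior[single] * cfg$species_specific_silencing_scale)
  silenced <- runif(n) < prior
  sil_label <- rep("none", n)
  both <- silenced & !single
  is_shared <- both & (runif(n) < cfg$shared_fraction)
  sil_label[is_shared] <- "shared"
  flip <- both & !is_shared
  sil_label[flip] <- ifelse(runif(sum(flip)) < 0.5,
                            "speciesA_only", "speciesB_only")
  sil_label[silenced & single] <-
    ifelse(own_sp[silenced & single] == "A", "speciesA_only", "speciesB_only")

  mdiv_mean <- .te_mdiv_mean[cls] * ifelse(silenced, 0.6, 1)
  milli_div <- round(.rnorm_trunc(n, mdiv_mean, .te_mdiv_sd[cls], 0, 400), 1)
  strand <- sample(c("+", "-"), n, replace = TRUE)

  ## project ancestor placements into each descendant
  proj <- function(maps) {
    out <- data.table::data.table(start = NA_integer_, end = NA_integer_,
                                  covered = 0L)[rep(1L, n)]
    for (ch in chroms) {
      at <- which(chrom == ch)
      if (!length(at)) next
      p <- .project_map(maps[[ch]], start0[at], end0[at])
      out[at, names(out) := p]
    }
    out
  }
  pa <- proj(gp$map_a)
  pb <- proj(gp$map_b)
  frac_a <- pa$covered / len
  frac_b <- pb$covered / len

  in_a <- (!single | own_sp == "A") & frac_a >= 0.5
  in_b <- (!single | own_sp == "B") & frac_b >= 0.5
  ## an orthologous placement eroded below 70% coverage in either lineage is
  ## no longer truthfully orthologous
  eroded <- orth_label == "orthologous" & (frac_a < 0.7 | frac_b < 0.7)
  orth_label[eroded] <- "non_orthologous"
  keep <- (in_a | in_b)
  te_id <- sprintf("te%05d", seq_len(n))

  truth <- data.table::data.table(
    te_id = te_id, chrom = chrom, anc_start = start0, anc_end = end0,
    name = name, family = family, te_class = cls, milli_div = milli_div,
    strand = strand,
    silencing_label = sil_label, orthology_label = orth_label,
    present_a = in_a, present_b = in_b,
    start_a = pa$start, end_a = pa$end,
    start_b = pb$start, end_b = pb$end)[keep]

  mk_table <- function(tr, which) {
    s <- if (which == "A") tr$start_a else tr$start_b
    e <- if (which == "A") tr$end_a else tr$end_b
    pres <- if (which == "A") tr$present_a else tr$present_b
    data.table::data.table(
      chrom = tr$chrom, start = s, end = e, name = tr$name,
      milli_div = tr$milli_div, strand = tr$strand,
      family = tr$family, te_class = tr$te_class, te_id = tr$te_id)[pres]
  }
  list(rmsk_a = mk_table(truth, "A"), rmsk_b = mk_table(truth, "B"),
       truth = truth)
}
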