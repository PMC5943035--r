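## ChIP / Input fragment simulation. Input fragments are uniform over the
## genome; ChIP fragments are a mixture of the same uniform background and
## enrichment over silenced TEs. Per-individual sequencing depth carries
## gamma noise, so counts over any fixed region are marginally negative
## binomial across individuals with the configured dispersion.

.uniform_fragments <- function(n, chrom_lens, frag_len) {
  if (n == 0L)
    return(data.table::data.table(chrom = character(0), start = integer(0),
                                  end = integer(0)))
  chrom <- sample(names(chrom_lens), n, replace = TRUE,
                  prob = chrom_lens / sum(chrom_lens))
  mid <- floor(runif(n) * chrom_lens[chrom])
  half <- frag_len %/% 2L
  s <- pmax(0L, as.integer(mid - half))
  e <- pmin(as.integer(chrom_lens[chrom]), as.integer(mid + half))
  data.table::data.table(chrom = chrom, start = s, end = e)[order(chrom, s)]
}

#' Simulate per-individual ChIP and Input fragment sets
#'
#' Input fragments are uniform over each genome. ChIP fragments add, on top
#' of the same background, `mean_frag_per_region` expected fragments per
#' silenced TE per individual; for species-specifically silenced TEs the
#' rate is multiplied by `2^species_effect_log2fc` in the enriched species
#' only. Each individual's depth is scaled by a gamma factor with the
#' configured negative binomial dispersion.
#'
#' @param cfg a [sim_config()]
#' @param gp output of [simulate_genome_pair()]
#' @param tes output of [simulate_te_annotations()]
#' @return a list with `chip` and `input` (named lists of
#'   `data.table(chrom, start, end)` per individual), `species` (named
#'   vector mapping individual to `"A"`/`"B"`), and `depth` factors
#' @export
simulate_chip_fragments <- function(cfg, gp, tes) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 2000L)
  n_a <- cfg$n_individuals_per_species[["A"]]
  n_b <- cfg$n_individuals_per_species[["B"]]
  .assert(n_a >= 1 && n_b >= 1, "need at least one individual per species")
  inds <- c(sprintf("A%02d", seq_len(n_a)), sprintf("B%02d", seq_len(n_b)))
  species <- setNames(rep(c("A", "B"), c(n_a, n_b)), inds)
  lens_a <- setNames(Biostrings::width(gp$genome_a), names(gp$genome_a))
  lens_b <- setNames(Biostrings::width(gp$genome_b), names(gp$genome_b))
  alpha <- cfg$nb_dispersion
  depth <- setNames(if (alpha > 0) {
    rgamma(length(inds), shape = 1 / alpha, rate = 1 / alpha)
  } else rep(1, length(inds)), inds)

  truth <- tes$truth
  te_rate <- function(sp) {
    pres <- if (sp == "A") truth$present_a else truth$present_b
    lab <- truth$silencing_label
    rate <- ifelse(lab == "none", 0, cfg$mean_frag_per_region)
    boost <- (sp == "A" & lab == "speciesA_only") |
      (sp == "B" & lab == "speciesB_only")
    rate[boost] <- rate[boost] * 2^cfg$species_effect_log2fc
    list(rate = rate[pres & rate > 0],
         chrom = truth$chrom[pres & rate > 0],
         start = (if (sp == "A") truth$start_a else truth$start_b)[pres & rate > 0],
         end = (if (sp == "A") truth$end_a else truth$end_b)[pres & rate > 0])
  }
  enr <- list(A = te_rate("A"), B = te_rate("B"))

  chip <- input <- setNames(vector("list", length(inds)), inds)
  for (ind in inds) {
    sp <- species[[ind]]
    lens <- if (sp == "A") lens_a else lens_b
    bg_mu <- cfg$background_frag_per_kb * sum(lens) / 1000 * depth[[ind]]
    input[[ind]] <- .uniform_fragments(rpois(1L, bg_mu), lens,
                                       cfg$fragment_len)
    bg <- .uniform_fragments(rpois(1L, bg_mu), lens, cfg$fragment_len)
    e <- enr[[sp]]
    cnt <- rpois(length(e$rate), e$rate * depth[[ind]])
    if (sum(cnt)) {
      idx <- rep(seq_along(cnt), cnt)
      mid <- e$start[idx] + floor(runif(sum(cnt)) * (e$end[idx] - e$start[idx]))
      half <- cfg$fragment_len %/% 2L
      sig <- data.table::data.table(
        chrom = e$chrom[idx],
        start = pmax(0L, as.integer(mid - half)),
        end = pmin(as.integer(lens[e$chrom[idx]]), as.integer(mid + half)))
      chip[[ind]] <- data.table::rbindlist(list(bg, sig))[order(chrom, start)]
    } else {
      chip[[ind]] <- bg
    }
  }
  list(chip = chip, input = input, species = species, depth = depth)
}
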