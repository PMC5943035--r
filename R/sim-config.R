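#' Configuration for the synthetic two-species cohort simulator
#'
#' Bundles every knob of the generative model: two genomes descended from a
#' common ancestor, hierarchical TE annotations with ground-truth silencing
#' and orthology labels, per-individual ChIP/Input fragment sets, and gene
#' expression counts optionally coupled to upstream TE silencing.
#'
#' Defaults emulate the study design this pipeline targets: a 10 + 7
#' individual cohort, about 1.2 percent sequence divergence split over the
#' two lineages, five TE classes with SVA and LTR elements carrying the
#' highest silencing priors, 80 percent of silenced TEs silenced in both
#' species, and a four-fold ChIP enrichment difference for species-specific
#' silencing.
#'
#' @param seed integer seed; the same seed yields byte-identical artifacts
#' @param n_chrom number of chromosomes
#' @param chrom_len chromosome length in bp
#' @param substitution_rate per-base substitution probability per lineage
#' @param indel_rate per-base indel event probability per lineage
#' @param mean_indel_len mean indel length in bp (geometric lengths)
#' @param n_te number of TE instances to place on the ancestor
#' @param te_class_weights named probabilities over classes
#'   LINE/SINE/LTR/DNA/SVA; must sum to 1
#' @param te_silencing_prior named per-class probability that an instance is
#'   silenced
#' @param shared_fraction probability a silenced orthologous TE is silenced
#'   in both species
#' @param species_effect_log2fc log2 ChIP enrichment difference applied in
#'   the enriched species for species-specific silencing
#' @param species_specific_silencing_scale multiplier on the silencing prior
#'   for TEs present in only one genome
#' @param nb_dispersion negative binomial dispersion of per-individual counts
#' @param mean_frag_per_region expected ChIP fragments per silenced TE per
#'   individual
#' @param background_frag_per_kb expected background fragments per kb per
#'   individual (both assays)
#' @param fragment_len fixed fragment length in bp (mirrors 200-300 bp
#'   size-selected ChIP fragments)
#' @param n_individuals_per_species length-2 named vector `c(A=, B=)`
#' @param n_genes number of genes
#' @param expression_coupling log2 expression effect per unit of
#'   species-specific upstream silencing (0 decouples expression from
#'   silencing)
#' @param expression_null_sd standard deviation of the null gene-effect
#'   distribution (log2 scale)
#' @param coupling_window upstream window in bp used to couple silencing to
#'   expression
#' @param species_specific_te_rate fraction of TEs inserted in only one
#'   genome
#' @param private_name_fraction among single-genome TEs, fraction given a
#'   type name absent from the other species' repertoire (ground-truth
#'   "species_specific"; the rest are "non-orthologous")
#' @return a validated object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_len = 1e6,
                       substitution_rate = 0.006,
                       indel_rate = 2e-4,
                       mean_indel_len = 3,
                       n_te = 5000L,
                       te_class_weights = c(LINE = 0.30, SINE = 0.40,
                                            LTR = 0.15, DNA = 0.10,
                                            SVA = 0.05),
                       te_silencing_prior = c(LINE = 0.12, SINE = 0.07,
                                              LTR = 0.22, DNA = 0.05,
                                              SVA = 0.30),
                       shared_fraction = 0.8,
                       species_effect_log2fc = 2,
                       species_specific_silencing_scale = 0.6,
                       nb_dispersion = 0.2,
                       mean_frag_per_region = 30,
                       background_frag_per_kb = 5,
                       fragment_len = 200L,
                       n_individuals_per_species = c(A = 10L, B = 7L),
                       n_genes = 400L,
                       expression_coupling = 0,
                       expression_null_sd = 0.15,
                       coupling_window = 10000L,
                       species_specific_te_rate = 0.10,
                       private_name_fraction = 0.5) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_len = chrom_len,
              substitution_rate = substitution_rate, indel_rate = indel_rate,
              mean_indel_len = mean_indel_len, n_te = as.integer(n_te),
              te_class_weights = te_class_weights,
              te_silencing_prior = te_silencing_prior,
              shared_fraction = shared_fraction,
              species_effect_log2fc = species_effect_log2fc,
              species_specific_silencing_scale = species_specific_silencing_scale,
              nb_dispersion = nb_dispersion,
              mean_frag_per_region = mean_frag_per_region,
              background_frag_per_kb = background_frag_per_kb,
              fragment_len = as.integer(fragment_len),
              n_individuals_per_species = n_individuals_per_species,
              n_genes = as.integer(n_genes),
              expression_coupling = expression_coupling,
              expression_null_sd = expression_null_sd,
              coupling_window = as.integer(coupling_window),
              species_specific_te_rate = species_specific_te_rate,
              private_name_fraction = private_name_fraction)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

.te_classes <- c("LINE", "SINE", "LTR", "DNA", "SVA")

validate_sim_config <- function(cfg) {
  .assert(is.finite(cfg$seed), "seed must be a finite integer")
  .assert(cfg$n_chrom >= 1, "n_chrom must be >= 1")
  .assert(is.numeric(cfg$chrom_len) && cfg$chrom_len > 0,
          "chrom_len must be positive")
  .assert(.is_prob(cfg$substitution_rate), "substitution_rate must be in [0,1]")
  .assert(.is_prob(cfg$indel_rate), "indel_rate must be in [0,1]")
  .assert(cfg$mean_indel_len >= 1, "mean_indel_len must be >= 1")
  .assert(setequal(names(cfg$te_class_weights), .te_classes),
          "te_class_weights must name classes %s",
          paste(.te_classes, collapse = "/"))
  .assert(.is_prob(cfg$te_class_weights) &&
            abs(sum(cfg$te_class_weights) - 1) < 1e-8,
          "te_class_weights must be probabilities summing to 1")
  .assert(setequal(names(cfg$te_silencing_prior), .te_classes) &&
            .is_prob(cfg$te_silencing_prior),
          "te_silencing_prior must be per-class probabilities")
  .assert(.is_prob(cfg$shared_fraction), "shared_fraction must be in [0,1]")
  .assert(.is_prob(cfg$species_specific_te_rate),
          "species_specific_te_rate must be in [0,1]")
  .assert(.is_prob(cfg$private_name_fraction),
          "private_name_fraction must be in [0,1]")
  .assert(cfg$species_specific_silencing_scale >= 0,
          "species_specific_silencing_scale must be >= 0")
  .assert(cfg$nb_dispersion >= 0, "nb_dispersion must be >= 0")
  .assert(cfg$mean_frag_per_region > 0, "mean_frag_per_region must be > 0")
  .assert(cfg$background_frag_per_kb > 0,
          "background_frag_per_kb must be > 0")
  .assert(cfg$fragment_len >= 1, "fragment_len must be >= 1")
  nis <- cfg$n_individuals_per_species
  .assert(length(nis) == 2 && all(nis >= 1) &&
            setequal(names(nis), c("A", "B")),
          "n_individuals_per_species must be c(A=, B=) with counts >= 1")
  .assert(cfg$n_genes >= 0, "n_genes must be >= 0")
  .assert(cfg$expression_null_sd >= 0, "expression_null_sd must be >= 0")
  .assert(cfg$coupling_window >= 1, "coupling_window must be >= 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d x %g bp chromosomes, %d TEs, %d+%d ",
                     "individuals, seed %d\n"),
              x$n_chrom, x$chrom_len, x$n_te,
              x$n_individuals_per_species[["A"]],
              x$n_individuals_per_species[["B"]], x$seed))
  invisible(x)
}
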