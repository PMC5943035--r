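#' Pipeline configuration
#'
#' Collects every pipeline threshold with the analysis defaults: 70 percent
#' lift match, mean mappability above 0.8, broad-peak q-value 0.1, 50
#' percent TE overlap, FDR 0.01 for both regions and expression, upstream
#' windows of 1/10/20/40 kb, and 50-mer mappability. Unknown keys are
#' rejected.
#'
#' @param ... overrides of the defaults listed above
#' @return a validated `pipeline_config` list
#' @export
pipeline_config <- function(...) {
  cfg <- list(min_match = 0.7, min_map = 0.8, peak_q = 0.1,
              peak_window = 100L, peak_gap = 0L,
              overlap_frac = 0.5, fdr_regions = 0.01, fdr_expression = 0.01,
              window_sizes = c(1000L, 10000L, 20000L, 40000L),
              k_mappability = 50L, association_window = 10000L,
              filter_quantiles = seq(0, 0.4, 0.1), n_perm = 999L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  .assert(!length(unknown), "unknown pipeline_config key(s): %s",
          paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  .assert(cfg$min_match > 0 && cfg$min_match <= 1,
          "min_match must be in (0,1]")
  .assert(.is_prob(cfg$min_map), "min_map must be in [0,1]")
  .assert(.is_prob(cfg$peak_q), "peak_q must be in [0,1]")
  .assert(.is_prob(cfg$overlap_frac), "overlap_frac must be in [0,1]")
  .assert(.is_prob(c(cfg$fdr_regions, cfg$fdr_expression)),
          "FDR levels must be in [0,1]")
  .assert(all(cfg$window_sizes > 0), "window sizes must be positive")
  .assert(cfg$k_mappability >= 1, "k_mappability must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' Pool per-individual peaks into per-species peak sets
#'
#' @param peaks_by_individual named list of peak `GRanges`
#' @param species named species map
#' @return list with elements `A` and `B` of union-merged `GRanges`
#' @export
pool_peaks <- function(peaks_by_individual, species) {
  out <- list()
  for (sp in c("A", "B")) {
    inds <- names(peaks_by_individual)[species[names(peaks_by_individual)] == sp]
    grl <- peaks_by_individual[inds]
    grl <- grl[vapply(grl, length, integer(1)) > 0]
    out[[sp]] <- if (length(grl)) {
      GenomicRanges::reduce(do.call(c, unname(lapply(grl, function(g) {
        S4Vectors::mcols(g) <- NULL
        g
      }))))
    } else GenomicRanges::GRanges()
  }
  out
}

#' Run the full comparative TE silencing pipeline on a synthetic cohort
#'
#' Executes simulate, per-individual broad-peak calling, orthologous region
#' construction, fragment counting, occupancy filtering, NB differential
#' enrichment, orthologous TE construction, TE silencing classification,
#' class-level analyses, gene-level silencing, differential expression, and
#' the silencing-vs-expression association. When `out` is given every
#' intermediate table is written as TSV along with a summary and a
#' METHODS.txt describing thresholds.
#'
#' @param sim a [sim_config()] describing the cohort
#' @param config a [pipeline_config()]
#' @param out optional output directory for the report bundle
#' @param mappability compute mappability tracks before filtering regions
#'   (default TRUE; the dominating cost on larger genomes)
#' @return a list with every stage's outputs and a `summary` data.table of
#'   category proportions per analysis level
#' @export
run_pipeline <- function(sim = sim_config(), config = pipeline_config(),
                         out = NULL, mappability = TRUE) {
  .assert(is(config, "pipeline_config"), "config must be a pipeline_config")
  cohort <- simulate_cohort(sim)
  gp <- cohort$gp
  lens_a <- setNames(Biostrings::width(gp$genome_a), names(gp$genome_a))
  lens_b <- setNames(Biostrings::width(gp$genome_b), names(gp$genome_b))
  track_a <- track_b <- NULL
  if (mappability) {
    track_a <- kmer_mappability(gp$genome_a, k = config$k_mappability)
    track_b <- kmer_mappability(gp$genome_b, k = config$k_mappability)
  }
  species <- cohort$frags$species
  peaks <- lapply(names(species), function(ind) {
    lens <- if (species[[ind]] == "A") lens_a else lens_b
    call_broad_peaks(cohort$frags$chip[[ind]], cohort$frags$input[[ind]],
                     lens, window = config$peak_window,
                     gap = config$peak_gap, q_max = config$peak_q)
  })
  names(peaks) <- names(species)
  regions <- build_orthologous_regions(peaks, species, gp$chain_ab,
                                       gp$chain_ba, track_a, track_b,
                                       min_match = config$min_match,
                                       min_map = config$min_map)
  counts <- count_fragments_in_regions(regions, cohort$frags$chip, species)
  counts <- filter_regions_by_occupancy(counts)
  diff_regions <- nb_differential(counts, species[colnames(counts)],
                                  alpha = config$fdr_regions,
                                  filter_quantiles = config$filter_quantiles)
  ortho <- orthologous_te_set(cohort$tes$rmsk_a, cohort$tes$rmsk_b,
                              gp$chain_ab, gp$chain_ba,
                              min_match = config$min_match,
                              min_bp_overlap = config$overlap_frac)
  parts <- partition_te_sets(cohort$tes$rmsk_a, cohort$tes$rmsk_b, ortho)
  calls <- classify_te_silencing(ortho, regions, diff_regions,
                                 min_frac = config$overlap_frac)
  species_peaks <- pool_peaks(peaks, species)
  class_overlap <- class_overlap_by_orthology(parts, species_peaks$A,
                                              species_peaks$B,
                                              min_frac = config$overlap_frac)
  class_enrich <- enrichment_by_class(calls)
  gene_sil <- gene_silencing_counts(cohort$expr$gene_table,
                                    config$association_window, ortho,
                                    regions, counts, lens_a,
                                    alpha = config$fdr_regions)
  expr <- filter_and_normalize_expression(cohort$expr$counts,
                                          cohort$expr$species)
  gene_de <- differential_expression(expr$filtered, cohort$expr$species,
                                     alpha = config$fdr_expression)
  assoc <- if (!is.null(gene_sil$diff) && nrow(gene_sil$diff) >= 3) {
    silencing_expression_association(gene_sil$diff, gene_de,
                                     alpha = config$fdr_expression,
                                     n_perm = config$n_perm,
                                     seed = sim$seed)
  } else NULL

  lvl <- function(level, labels) {
    tb <- table(factor(labels, levels = c("shared", "A_enriched",
                                          "B_enriched", "non_overlapping")))
    data.table::data.table(level = level, category = names(tb),
                           n = as.integer(tb),
                           proportion = as.numeric(tb) / max(1, sum(tb)))
  }
  summary <- data.table::rbindlist(list(
    lvl("regions", diff_regions$category[diff_regions$category != "not_tested"]),
    lvl("tes", calls$status),
    if (!is.null(gene_sil$diff)) lvl("gene_windows", gene_sil$diff$category)))
  res <- list(cohort = cohort, peaks = peaks, regions = regions,
              counts = counts, diff_regions = diff_regions, ortho = ortho,
              parts = parts, calls = calls, class_overlap = class_overlap,
              class_enrich = class_enrich, gene_sil = gene_sil,
              expression = expr, gene_de = gene_de, association = assoc,
              species_peaks = species_peaks, summary = summary,
              config = config)
  if (!is.null(out)) .write_bundle(res, out)
  res
}

.write_bundle <- function(res, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  fw <- function(x, f) data.table::fwrite(x, file.path(out, f), sep = "\t")
  fw(res$regions, "orthologous_regions.tsv")
  fw(data.table::as.data.table(res$counts, keep.rownames = "region_id"),
     "region_counts.tsv")
  fw(res$diff_regions, "differential_regions.tsv")
  fw(res$ortho, "orthologous_tes.tsv")
  fw(res$calls, "te_silencing_calls.tsv")
  fw(res$class_overlap$proportions, "class_overlap_by_orthology.tsv")
  fw(res$class_enrich, "class_enrichment.tsv")
  if (!is.null(res$gene_sil$diff)) fw(res$gene_sil$diff, "gene_silencing.tsv")
  fw(res$gene_de, "differential_expression.tsv")
  fw(res$summary, "summary.tsv")
  writeLines(c(
    "Methods summary",
    sprintf("Lift minimum match fraction: %.2f", res$config$min_match),
    sprintf("Mean mappability threshold (exclusive): %.2f", res$config$min_map),
    sprintf("Broad peak q-value threshold: %.2f (window %d bp, gap %d bp)",
            res$config$peak_q, res$config$peak_window, res$config$peak_gap),
    sprintf("TE overlap fraction: %.2f", res$config$overlap_frac),
    sprintf("Region / expression FDR: %.2f / %.2f",
            res$config$fdr_regions, res$config$fdr_expression),
    sprintf("k-mer mappability k: %d", res$config$k_mappability),
    "Peak calling: windowed Poisson broad caller (simplified stand-in for dedicated broad-domain callers).",
    "Differential testing: in-package NB Wald engine for both ChIP and RNA counts.",
    "Dispersion shrinkage: geometric weight toward a 1/mu trend (w = 0.5)."),
    file.path(out, "METHODS.txt"))
  invisible(out)
}
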