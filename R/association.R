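#' Gene-level TE silencing counts from upstream windows
#'
#' For each gene, the distinct orthologous H3K9me3 regions overlapping a TE
#' inside the gene's upstream window are collected and their per-individual
#' counts summed; a region containing multiple TEs in the window is counted
#' once. Genes whose window contains no TE-overlapping region are excluded.
#' The summed gene-level matrices are tested for a species effect with the
#' NB engine.
#'
#' @param gene_table one row per gene (`gene_id`, `chrom`, `strand`, `tss`),
#'   genome-A coordinates
#' @param window_size upstream window in bp
#' @param tes TE table in genome-A coordinates (`chrom_a`, `start_a`,
#'   `end_a`)
#' @param regions region table from [build_orthologous_regions()]
#' @param matrix region count matrix (rownames = region ids)
#' @param chrom_lens named chromosome lengths
#' @param alpha FDR level for categories (default 0.01)
#' @return list with `counts` (gene-level summed matrix), `n_regions_used`
#'   per gene, and `diff` (classified NB results per gene)
#' @export
gene_silencing_counts <- function(gene_table, window_size, tes, regions,
                                  matrix, chrom_lens, alpha = 0.01) {
  species <- attr(matrix, "species")
  .assert(!is.null(species), "count matrix must carry a species attribute")
  reg <- regions[regions$region_id %in% rownames(matrix)]
  te_gr <- gi(tes$chrom_a, tes$start_a, tes$end_a)
  reg_gr <- gi(reg$chrom_a, reg$start_a, reg$end_a)
  te_reg <- GenomicRanges::findOverlaps(te_gr, reg_gr)
  wins <- .upstream_windows(gene_table$tss, gene_table$strand, window_size,
                            chrom_lens[gene_table$chrom], gene_table$chrom)
  win_te <- GenomicRanges::findOverlaps(wins$gr, te_gr)
  ## gene -> TEs in window -> distinct regions overlapping those TEs
  link <- merge(
    data.table::data.table(gene = wins$idx[S4Vectors::queryHits(win_te)],
                           te = S4Vectors::subjectHits(win_te)),
    data.table::data.table(te = S4Vectors::queryHits(te_reg),
                           region = S4Vectors::subjectHits(te_reg)),
    by = "te", allow.cartesian = TRUE)
  link <- unique(link[, c("gene", "region")])
  if (!nrow(link))
    return(list(counts = matrix[0, , drop = FALSE],
                n_regions_used = integer(0), diff = NULL))
  counts <- rowsum(matrix[reg$region_id[link$region], , drop = FALSE],
                   group = gene_table$gene_id[link$gene])
  counts <- counts[order(rownames(counts)), , drop = FALSE]
  storage.mode(counts) <- "integer"
  nreg <- link[, list(n = .N), by = "gene"]
  n_regions_used <- setNames(nreg$n, gene_table$gene_id[nreg$gene])
  diff <- classify_enrichment(
    nb_differential(counts, species[colnames(counts)], alpha = alpha,
                    filter_quantiles = NULL), alpha)
  list(counts = counts, n_regions_used = n_regions_used, diff = diff)
}

#' Filter and normalize an expression count matrix
#'
#' Retains genes with positive counts in more than 10/17 of individuals
#' (the ratio generalizes to other cohort sizes, rounding the threshold
#' down), quantile-normalizes counts across individuals, and returns
#' log2 counts-per-million with a pseudocount of 1.
#'
#' @param gene_counts genes x individuals count matrix
#' @param species `"A"`/`"B"` per column
#' @return list with `filtered` (raw counts of retained genes), `qnorm`
#'   (quantile-normalized counts) and `log_expression` (log2 CPM of the
#'   normalized counts)
#' @export
filter_and_normalize_expression <- function(gene_counts, species) {
  n <- ncol(gene_counts)
  .assert(n >= 4, "need at least 4 individuals")
  thr <- floor(n * 10 / 17)
  keep <- rowSums(gene_counts > 0) > thr
  filtered <- gene_counts[keep, , drop = FALSE]
  qn <- if (nrow(filtered) >= 2) {
    limma::normalizeQuantiles(filtered, ties = TRUE)
  } else filtered
  cpm <- sweep(qn, 2, pmax(colSums(qn), 1), "/") * 1e6
  list(filtered = filtered, qnorm = qn,
       log_expression = log2(cpm + 1), species = species)
}

#' Differential expression between species
#'
#' Runs the package's NB engine on the occupancy-filtered raw counts and
#' classifies genes at the given FDR. One engine serves both ChIP regions
#' and RNA counts.
#'
#' @param filtered raw counts of retained genes
#' @param species `"A"`/`"B"` per column
#' @param alpha FDR level (default 0.01)
#' @return classified results data.table
#' @export
differential_expression <- function(filtered, species, alpha = 0.01) {
  nb_differential(filtered, species, alpha = alpha, filter_quantiles = NULL)
}

#' Associate TE silencing divergence with gene expression divergence
#'
#' Joins gene-level silencing results with differential expression and
#' reports: per-silencing-category expression log2FC distributions with
#' pairwise rank-sum tests; a cross-tabulation of silencing category by
#' differential-expression status with a chi-squared test; the Pearson
#' correlation (permutation p) between silencing and expression log2FC;
#' and counts of sign-consistent versus sign-inconsistent genes.
#'
#' @param gene_silencing `diff` table from [gene_silencing_counts()]
#' @param gene_de results from [differential_expression()]
#' @param alpha FDR defining the DE status (default 0.01)
#' @param n_perm,seed permutation settings for the correlation
#' @return list with `merged`, `by_category`, `category_tests`,
#'   `de_crosstab`, `crosstab_test`, `correlation`, `sign_consistency`
#' @export
silencing_expression_association <- function(gene_silencing, gene_de,
                                             alpha = 0.01, n_perm = 999L,
                                             seed = 1L) {
  m <- merge(
    data.table::data.table(gene_id = gene_silencing$feature_id,
                           sil_log2fc = gene_silencing$log2fc,
                           sil_category = gene_silencing$category),
    data.table::data.table(gene_id = gene_de$feature_id,
                           expr_log2fc = gene_de$log2fc,
                           expr_padj = gene_de$padj),
    by = "gene_id")
  .assert(nrow(m) > 0, "no genes shared between silencing and expression")
  by_cat <- m[, list(n = .N, median_expr_log2fc = median(expr_log2fc,
                                                         na.rm = TRUE)),
              by = "sil_category"]
  cats <- unique(m$sil_category)
  pairs <- if (length(cats) >= 2) utils::combn(sort(cats), 2) else
    matrix(character(0), 2, 0)
  cat_tests <- data.table::rbindlist(lapply(seq_len(ncol(pairs)), function(j) {
    a <- m$expr_log2fc[m$sil_category == pairs[1, j]]
    b <- m$expr_log2fc[m$sil_category == pairs[2, j]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    rs <- rank_sum_test(a, b)
    data.table::data.table(group1 = pairs[1, j], group2 = pairs[2, j],
                           U = rs$U, p = rs$p)
  }))
  de_status <- ifelse(!is.na(m$expr_padj) & m$expr_padj < alpha, "DE",
                      "not_DE")
  tab <- table(m$sil_category, de_status)
  crosstab_test <- if (nrow(tab) >= 2 && ncol(tab) >= 2 &&
                         all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    chi_squared_test(tab)
  } else NULL
  cc <- complete.cases(m$sil_log2fc, m$expr_log2fc)
  correlation <- if (sum(cc) >= 3 && sd(m$sil_log2fc[cc]) > 0 &&
                       sd(m$expr_log2fc[cc]) > 0) {
    pearson_corr_permutation(m$sil_log2fc[cc], m$expr_log2fc[cc],
                             n_perm = n_perm, seed = seed)
  } else NULL
  nz <- cc & m$sil_log2fc != 0 & m$expr_log2fc != 0
  sign_consistency <- c(
    opposite = sum(sign(m$sil_log2fc[nz]) != sign(m$expr_log2fc[nz])),
    same = sum(sign(m$sil_log2fc[nz]) == sign(m$expr_log2fc[nz])))
  list(merged = m, by_category = by_cat, category_tests = cat_tests,
       de_crosstab = tab, crosstab_test = crosstab_test,
       correlation = correlation, sign_consistency = sign_consistency)
}

#' RPKM of agglomerated TE-type expression
#'
#' `RPKM = reads * 1e9 / (agglomerated_length * total_exonic_reads)`,
#' where the agglomerated length sums all annotated genomic copies of the
#' type; a type is expressed when RPKM is strictly greater than 1.
#'
#' @param reads read counts per TE type
#' @param agg_length agglomerated length in bp per type
#' @param total_exonic_reads library total exonic reads
#' @return data.table with `rpkm` and `expressed`
#' @export
te_type_rpkm <- function(reads, agg_length, total_exonic_reads) {
  .assert(all(agg_length > 0), "agglomerated lengths must be positive")
  .assert(all(total_exonic_reads > 0), "total exonic reads must be positive")
  rpkm <- reads * 1e9 / (agg_length * total_exonic_reads)
  data.table::data.table(reads = reads, agg_length = agg_length,
                         rpkm = rpkm, expressed = rpkm > 1)
}

#' H3K9me3 overlap of a curated gene set
#'
#' Flags genes of a curated set (e.g. KRAB-ZNF genes) whose body is covered
#' at least half by orthologous H3K9me3 regions (`body_half`), or whose
#' 1 kb window centred on the TSS is covered at least half
#' (`tss_1kb_half`), and assigns each overlapping gene the category of its
#' largest-overlap region. Unknown gene ids are listed and excluded.
#'
#' @param gene_set character vector of gene ids
#' @param gene_table gene table with `gene_id`, `chrom`, `strand`, `tss`,
#'   `tx_start`, `tx_end`
#' @param regions region table
#' @param diff classified region results
#' @param mode `body_half` or `tss_1kb_half`
#' @return list with `flags` (per-gene data.table) and `unknown`
#' @export
gene_set_h3k9me3_overlap <- function(gene_set, gene_table, regions, diff,
                                     mode = c("body_half", "tss_1kb_half")) {
  mode <- match.arg(mode)
  unknown <- setdiff(gene_set, gene_table$gene_id)
  g <- gene_table[gene_table$gene_id %in% gene_set]
  if (mode == "body_half") {
    s <- g$tx_start; e <- g$tx_end
  } else {
    s <- pmax(0, g$tss - 500L); e <- g$tss + 500L
  }
  reg_gr <- gi(regions$chrom_a, regions$start_a, regions$end_a)
  fr <- .covered_fraction(g$chrom, as.integer(s), as.integer(e), reg_gr)
  span_gr <- gi(g$chrom, as.integer(s), as.integer(e))
  cat_by_region <- setNames(diff$category, diff$feature_id)
  assigned <- rep(NA_character_, nrow(g))
  category <- rep(NA_character_, nrow(g))
  hit <- which(fr >= 0.5)
  if (length(hit)) {
    ov <- GenomicRanges::findOverlaps(span_gr[hit], reg_gr)
    q <- S4Vectors::queryHits(ov); sbj <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(span_gr[hit])[q], IRanges::ranges(reg_gr)[sbj]))
    cand <- data.table::data.table(q = q, rid = regions$region_id[sbj],
                                   w = w)
    data.table::setorderv(cand, c("q", "w", "rid"), c(1L, -1L, 1L))
    cand <- cand[!duplicated(cand$q)]
    assigned[hit[cand$q]] <- cand$rid
    ct <- cat_by_region[cand$rid]
    ct[is.na(ct) | ct == "not_tested"] <- "shared"
    category[hit[cand$q]] <- ct
  }
  list(flags = data.table::data.table(gene_id = g$gene_id,
                                      covered_fraction = fr,
                                      overlapping = fr >= 0.5,
                                      assigned_region = assigned,
                                      category = category),
       unknown = unknown)
}

#' Non-orthologous TE silencing versus expression divergence
#'
#' In each species' own coordinates, genes are labelled `silent` when all
#' non-orthologous TEs in the upstream window overlap that species' H3K9me3
#' peaks (by at least `min_frac` of their length) and `non_silent` when at
#' least one does not; genes with no non-orthologous TE in the window are
#' excluded. Absolute expression divergence is compared between the labels
#' by rank-sum per species and window size.
#'
#' @param nonortho_by_species list `A`/`B` of non-orthologous TE tables
#'   (`chrom`, `start`, `end`) in each species' coordinates
#' @param peaks_by_species list `A`/`B` of pooled peak `GRanges`
#' @param gene_tables list `A`/`B` of gene tables in each species'
#'   coordinates (genome-B TSSs obtained by reciprocal lifting)
#' @param window_sizes upstream window sizes in bp
#' @param gene_de differential expression results
#' @param chrom_lens_by_species list `A`/`B` of named chromosome lengths
#' @param min_frac overlap threshold (default 0.5)
#' @return data.table per species x window with group sizes and rank-sum p
#' @export
nonorthologous_te_association <- function(nonortho_by_species,
                                          peaks_by_species, gene_tables,
                                          window_sizes, gene_de,
                                          chrom_lens_by_species,
                                          min_frac = 0.5) {
  abs_lfc <- setNames(abs(gene_de$log2fc), gene_de$feature_id)
  rows <- list()
  for (sp in c("A", "B")) {
    te <- nonortho_by_species[[sp]]
    if (is.null(te) || !nrow(te)) next
    fr <- .covered_fraction(te$chrom, te$start, te$end,
                            peaks_by_species[[sp]])
    te_sil <- fr >= min_frac
    te_gr <- .te_gr(te)
    g <- gene_tables[[sp]]
    lens <- chrom_lens_by_species[[sp]]
    for (ws in window_sizes) {
      wins <- .upstream_windows(g$tss, g$strand, ws, lens[g$chrom], g$chrom)
      ov <- GenomicRanges::findOverlaps(wins$gr, te_gr)
      if (!length(ov)) next
      lab <- tapply(te_sil[S4Vectors::subjectHits(ov)],
                    S4Vectors::queryHits(ov), all)
      gene_ids <- g$gene_id[wins$idx[as.integer(names(lab))]]
      d <- data.table::data.table(gene_id = gene_ids,
                                  silent = as.logical(lab),
                                  abs_lfc = abs_lfc[gene_ids])
      d <- d[!is.na(d$abs_lfc)]
      if (sum(d$silent) < 2 || sum(!d$silent) < 2) next
      rs <- rank_sum_test(d$abs_lfc[d$silent], d$abs_lfc[!d$silent])
      rows[[length(rows) + 1L]] <- data.table::data.table(
        species = sp, window = ws, n_silent = sum(d$silent),
        n_non_silent = sum(!d$silent),
        median_silent = median(d$abs_lfc[d$silent]),
        median_non_silent = median(d$abs_lfc[!d$silent]),
        U = rs$U, p = rs$p)
    }
  }
  if (!length(rows)) return(data.table::data.table())
  data.table::rbindlist(rows)
}
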