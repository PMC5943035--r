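#' Classify TE silencing against orthologous H3K9me3 regions
#'
#' A TE whose genome-A span is covered by orthologous H3K9me3 regions over
#' at least `min_frac` of its length is "overlapping" and inherits the
#' differential-enrichment category (shared / A_enriched / B_enriched) of
#' the single region with the largest base overlap (ties to the smaller
#' region id); all other TEs are `non_overlapping`.
#'
#' @param tes data.table of TEs with genome-A coordinates (`chrom_a`,
#'   `start_a`, `end_a`; the orthologous set from [orthologous_te_set()])
#' @param regions region table from [build_orthologous_regions()]
#' @param diff classified [nb_wald_test()] results keyed by `feature_id` =
#'   `region_id`
#' @param min_frac minimum covered fraction of TE length (default 0.5)
#' @return the TEs with `overlap_fraction`, `status`, `assigned_region` and
#'   the assigned region's `region_log2fc` appended
#' @export
classify_te_silencing <- function(tes, regions, diff, min_frac = 0.5) {
  out <- data.table::copy(tes)
  n <- nrow(out)
  te_gr <- gi(out$chrom_a, out$start_a, out$end_a)
  keep_reg <- regions[regions$region_id %in% diff$feature_id]
  cat_by_region <- setNames(diff$category, diff$feature_id)
  lfc_by_region <- setNames(diff$log2fc, diff$feature_id)
  out[, c("overlap_fraction", "status", "assigned_region", "region_log2fc") :=
        list(0, "non_overlapping", NA_character_, NA_real_)]
  if (!nrow(keep_reg) || !n) return(out)
  reg_gr <- gi(keep_reg$chrom_a, keep_reg$start_a, keep_reg$end_a)
  ## fraction of TE length covered by the union of regions
  out[, "overlap_fraction" := .covered_fraction(out$chrom_a, out$start_a,
                                                out$end_a, reg_gr)]
  hit <- which(out$overlap_fraction >= min_frac)
  if (length(hit)) {
    ov <- GenomicRanges::findOverlaps(te_gr[hit], reg_gr)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(te_gr[hit])[q], IRanges::ranges(reg_gr)[s]))
    cand <- data.table::data.table(q = q, s = s, w = w,
                                   rid = keep_reg$region_id[s])
    data.table::setorderv(cand, c("q", "w", "rid"), c(1L, -1L, 1L))
    cand <- cand[!duplicated(cand$q)]
    out[hit[cand$q], c("assigned_region", "region_log2fc") :=
          list(cand$rid, lfc_by_region[cand$rid])]
    st <- cat_by_region[cand$rid]
    st[is.na(st) | st == "not_tested"] <- "shared"
    out[hit[cand$q], "status" := st]
  }
  out[]
}

## overlap fractions of TE spans against a union of intervals, by species'
## own coordinates
.covered_fraction <- function(chrom, start0, end0, feature_gr) {
  te_gr <- gi(chrom, start0, end0)
  red <- GenomicRanges::reduce(feature_gr)
  ov <- GenomicRanges::findOverlaps(te_gr, red)
  covered <- numeric(length(te_gr))
  if (length(ov)) {
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(te_gr)[S4Vectors::queryHits(ov)],
      IRanges::ranges(red)[S4Vectors::subjectHits(ov)]))
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    covered[as.integer(names(agg))] <- agg
  }
  covered / (end0 - start0)
}

#' Within-species TE overlap proportions by orthology category
#'
#' For each species and TE class, the fraction of orthologous,
#' non-orthologous, and species-specific instances that overlap that
#' species' own H3K9me3 peak set by at least `min_frac` of their length,
#' with a chi-squared test across orthology categories per class. Empty
#' categories are reported as missing (`NA`), mirroring TE classes with no
#' species-specific annotations.
#'
#' @param parts output of [partition_te_sets()]
#' @param peaks_a,peaks_b per-species pooled peak `GRanges`
#' @param min_frac overlap threshold (default 0.5)
#' @return list with `proportions` (long data.table) and `tests` (per
#'   species x class chi-squared results)
#' @export
class_overlap_by_orthology <- function(parts, peaks_a, peaks_b,
                                       min_frac = 0.5) {
  sets <- list(
    A = list(orthologous = parts$orthologous[, list(
               chrom = chrom_a, start = start_a, end = end_a,
               te_class = te_class)],
             non_orthologous = parts$non_orthologous_a[
               !parts$non_orthologous_a$name %in%
                 parts$species_specific_a$name,
               list(chrom, start, end, te_class)],
             species_specific = parts$species_specific_a[,
               list(chrom, start, end, te_class)]),
    B = list(orthologous = parts$orthologous[, list(
               chrom = chrom_b, start = start_b, end = end_b,
               te_class = te_class)],
             non_orthologous = parts$non_orthologous_b[
               !parts$non_orthologous_b$name %in%
                 parts$species_specific_b$name,
               list(chrom, start, end, te_class)],
             species_specific = parts$species_specific_b[,
               list(chrom, start, end, te_class)]))
  peaks <- list(A = peaks_a, B = peaks_b)
  rows <- list()
  for (sp in c("A", "B")) {
    for (cat in names(sets[[sp]])) {
      d <- sets[[sp]][[cat]]
      for (cl in .te_classes) {
        dc <- d[d$te_class == cl]
        if (!nrow(dc)) {
          rows[[length(rows) + 1L]] <- data.table::data.table(
            species = sp, te_class = cl, orthology = cat,
            n = 0L, n_overlap = NA_integer_, proportion = NA_real_)
          next
        }
        fr <- .covered_fraction(dc$chrom, dc$start, dc$end, peaks[[sp]])
        rows[[length(rows) + 1L]] <- data.table::data.table(
          species = sp, te_class = cl, orthology = cat,
          n = nrow(dc), n_overlap = sum(fr >= min_frac),
          proportion = mean(fr >= min_frac))
      }
    }
  }
  prop <- data.table::rbindlist(rows)
  tests <- prop[!is.na(prop$proportion),
                if (.N >= 2 && sum(n_overlap) > 0 && sum(n - n_overlap) > 0) {
                  tb <- rbind(n_overlap, n - n_overlap)
                  ct <- chi_squared_test(tb)
                  list(X2 = ct$X2, df = ct$df, p = ct$p)
                }, by = c("species", "te_class")]
  list(proportions = prop, tests = tests)
}

#' Per-class enrichment of H3K9me3 overlap versus the genome background
#'
#' For each TE class, a 2x2 table (in-class vs out-of-class by overlapping
#' vs not) is tested by Pearson's chi-squared, with BH adjustment across
#' classes; the odds ratio sign distinguishes enrichment (e.g. LTR, SVA)
#' from depletion.
#'
#' @param calls output of [classify_te_silencing()]
#' @return data.table per class with counts, proportions, `X2`, `p`, `padj`
#'   and `direction`
#' @export
enrichment_by_class <- function(calls) {
  .assert(length(unique(calls$te_class)) >= 2, "need at least 2 TE classes")
  ov <- calls$status != "non_overlapping"
  rows <- lapply(sort(unique(calls$te_class)), function(cl) {
    inc <- calls$te_class == cl
    tb <- matrix(c(sum(inc & ov), sum(inc & !ov),
                   sum(!inc & ov), sum(!inc & !ov)), 2, byrow = TRUE)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) {
      warning("degenerate table for class ", cl, ", skipped")
      return(NULL)
    }
    ct <- chi_squared_test(tb)
    data.table::data.table(
      te_class = cl, n = sum(inc), prop_overlap = mean(ov[inc]),
      background_prop = mean(ov[!inc]), X2 = ct$X2, p = ct$p,
      direction = ifelse(mean(ov[inc]) > mean(ov[!inc]),
                         "enriched", "depleted"))
  })
  out <- data.table::rbindlist(rows)
  out[, "padj" := bh_adjust(out$p)]
  out[]
}

#' Length-matched control for overlap proportions
#'
#' Artificially extends each non-overlapping TE symmetrically to the median
#' length of H3K9me3-marked TEs (clipping at chromosome ends) and recomputes
#' the overlap proportion under the same `min_frac` rule, to test whether
#' longer TEs overlap more often by chance alone.
#'
#' @param nonoverlapping_tes data.table with `chrom_a`, `start_a`, `end_a`
#' @param regions region table
#' @param target_median target length in bp (at least the median input
#'   length)
#' @param chrom_lens named chromosome lengths for clipping
#' @param min_frac overlap threshold (default 0.5)
#' @return list with `original`, `extended` proportions and the extended
#'   table
#' @export
length_matched_control <- function(nonoverlapping_tes, regions,
                                   target_median, chrom_lens,
                                   min_frac = 0.5) {
  te <- nonoverlapping_tes
  .assert(target_median >= median(te$end_a - te$start_a),
          "target_median below the median input length")
  reg_gr <- gi(regions$chrom_a, regions$start_a, regions$end_a)
  f0 <- .covered_fraction(te$chrom_a, te$start_a, te$end_a, reg_gr)
  len <- te$end_a - te$start_a
  grow <- pmax(0, target_median - len)
  s <- pmax(0, te$start_a - floor(grow / 2))
  e <- pmin(chrom_lens[te$chrom_a], te$end_a + ceiling(grow / 2))
  f1 <- .covered_fraction(te$chrom_a, as.integer(s), as.integer(e), reg_gr)
  ext <- data.table::copy(te)
  ext[, c("start_a", "end_a") := list(as.integer(s), as.integer(e))]
  list(original = mean(f0 >= min_frac), extended = mean(f1 >= min_frac),
       extended_tes = ext)
}

#' Compare TE properties across silencing groups
#'
#' Summarizes a property (TE length, milliDiv divergence, or distance to
#' the closest TSS) per group and tests the focal contrasts by rank-sum:
#' shared versus non-overlapping for category grouping, and regions with
#' absolute species log2 fold change below versus at or above `lfc_split`
#' for the effect-size grouping.
#'
#' @param calls output of [classify_te_silencing()]
#' @param property one of `length`, `milli_div`, `tss_distance`
#' @param grouping `category` or `abs_log2fc_split`
#' @param tss positions (data.table `chrom`, `tss`), required for
#'   `tss_distance`
#' @param lfc_split absolute log2 fold-change split point (default 1, i.e.
#'   two-fold)
#' @return list with `summary` (per-group median/IQR/n) and `tests`
#' @export
property_compare <- function(calls, property = c("length", "milli_div",
                                                 "tss_distance"),
                             grouping = c("category", "abs_log2fc_split"),
                             tss = NULL, lfc_split = 1) {
  property <- match.arg(property)
  grouping <- match.arg(grouping)
  val <- switch(property,
    length = calls$end_a - calls$start_a,
    milli_div = calls$milli_div,
    tss_distance = {
      .assert(!is.null(tss), "tss table required for tss_distance")
      te_gr <- gi(calls$chrom_a, calls$start_a, calls$end_a)
      tss_gr <- gi(tss$chrom, tss$tss, tss$tss + 1L)
      d <- GenomicRanges::distanceToNearest(te_gr, tss_gr)
      dv <- rep(NA_real_, nrow(calls))
      dv[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
      dv
    })
  grp <- if (grouping == "category") calls$status else
    ifelse(is.na(calls$region_log2fc), NA_character_,
           ifelse(abs(calls$region_log2fc) < lfc_split,
                  sprintf("abs_lfc_lt_%g", lfc_split),
                  sprintf("abs_lfc_ge_%g", lfc_split)))
  keep <- !is.na(grp) & !is.na(val)
  dt <- data.table::data.table(group = grp[keep], value = val[keep])
  summary <- dt[, list(n = .N, median = as.numeric(median(value)),
                       q25 = as.numeric(quantile(value, 0.25)),
                       q75 = as.numeric(quantile(value, 0.75))),
                by = "group"]
  contrasts <- if (grouping == "category") {
    list(c("shared", "non_overlapping"))
  } else {
    list(c(sprintf("abs_lfc_lt_%g", lfc_split),
           sprintf("abs_lfc_ge_%g", lfc_split)))
  }
  tests <- data.table::rbindlist(lapply(contrasts, function(ct) {
    a <- dt$value[dt$group == ct[1]]; b <- dt$value[dt$group == ct[2]]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    rs <- rank_sum_test(a, b)
    data.table::data.table(group1 = ct[1], group2 = ct[2],
                           U = rs$U, p = rs$p)
  }))
  list(summary = summary, tests = tests)
}

#' Overlap of silencing calls with an external annotation
#'
#' Per silencing category, the fraction of TEs intersecting the annotation
#' either by at least 1 bp (`any_bp`, the chromatin-state convention) or by
#' at least half the TE's length (`half_length`, the functional-mark
#' convention), with a chi-squared test across categories.
#'
#' @param calls output of [classify_te_silencing()]
#' @param annotation `GRanges` (genome-A coordinates)
#' @param mode `any_bp` or `half_length`
#' @return list with `proportions` and `test`
#' @export
annotate_overlap <- function(calls, annotation, mode = c("any_bp",
                                                         "half_length")) {
  mode <- match.arg(mode)
  .assert(length(annotation) > 0, "annotation is empty")
  fr <- .covered_fraction(calls$chrom_a, calls$start_a, calls$end_a,
                          annotation)
  hit <- if (mode == "any_bp") fr > 0 else fr >= 0.5
  dt <- data.table::data.table(status = calls$status, hit = hit)
  prop <- dt[, list(n = .N, n_hit = sum(hit), proportion = mean(hit)),
             by = "status"]
  test <- if (nrow(prop) >= 2 && sum(prop$n_hit) > 0 &&
                sum(prop$n - prop$n_hit) > 0) {
    chi_squared_test(rbind(prop$n_hit, prop$n - prop$n_hit))
  } else NULL
  list(proportions = prop, test = test)
}

#' Correlation between family copy number and overlap proportion
#'
#' Tests whether TE families with more genomic copies are more (or less)
#' likely to overlap H3K9me3, using Pearson correlation across families
#' with a permutation p-value.
#'
#' @param calls output of [classify_te_silencing()]
#' @param n_perm permutations (default 999)
#' @param seed RNG seed
#' @param min_family_size families with fewer instances are dropped
#' @return list with `by_family`, `r`, `p`
#' @export
copy_number_vs_overlap <- function(calls, n_perm = 999L, seed = 1L,
                                   min_family_size = 1L) {
  fam <- calls[, list(copy_number = .N,
                      proportion = mean(status != "non_overlapping")),
               by = "family"]
  fam <- fam[fam$copy_number >= min_family_size]
  .assert(nrow(fam) >= 3, "need at least 3 families")
  ct <- pearson_corr_permutation(fam$copy_number, fam$proportion,
                                 n_perm = n_perm, seed = seed)
  list(by_family = fam, r = ct$r, p = ct$p)
}
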