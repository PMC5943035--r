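---
title: "Methods: comparative H3K9me3 TE silencing with k9te"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative H3K9me3 TE silencing with k9te}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

H3K9me3 is the repressive histone mark that silences transposable
elements (TEs). Comparing TE silencing between two closely related
species means reconciling two genome assemblies, two RepeatMasker-style
annotations, and per-individual ChIP cohorts of different sizes, then
asking three questions: which genomic regions carry H3K9me3 in both
species, which TEs sit under those regions, and where does the *degree*
of silencing differ between species — and does that divergence propagate
to neighbouring gene expression?

`k9te` implements this as a typed pipeline over `GRanges` intervals
(0-based half-open at the file boundary), with every stage exposed as an
ordinary function and a synthetic-cohort generator that provides ground
truth for all of it.

# Cross-genome interval mapping

All lifting runs through UCSC chain alignments. An interval maps when at
least `min_match` (default 0.7, i.e. the usual 70 percent sequence-match
threshold of reciprocal-best liftOver practice) of its bases fall inside
aligned blocks of a chain, and exactly one chain reaches that coverage —
two qualifying chains mean the locus is ambiguous and the interval is
dropped with reason `nonreciprocal`. The mapped interval is the envelope
of the per-base images; base identity is not re-examined, since the
chains are assumed to come from a reciprocal-best pipeline. "Reciprocally
mapped" additionally requires the round-trip image to overlap the
original by at least `min_match` of its length. The round-trip fraction
is not separately tunable by design: one threshold governs the forward
lift, the back lift and the round-trip overlap, which keeps the filter
interpretable and is exposed in `pipeline_config(min_match = )`.

Minus-strand chains are supported by reflecting target coordinates into
plus-strand space; lifted intervals are always reported on the target's
plus strand with the source strand kept as metadata.

Mappability is per-base `1/n` with `n` the number of exact occurrences of
the k-mer (default `k = 50` bp) starting at that base, counted on both
strands. Exact matching is a deliberate simplification of
mismatch-tolerant mappability algorithms: on the synthetic genomes the
two agree except at recently duplicated sequence, and exactness makes the
occurrence-counting oracle in the tests a true independent check. The
trailing `k − 1` bases of each chromosome inherit the score of the last
full k-mer start so that interval means are always defined. Regions must
average strictly above `min_map = 0.8` in each species.

# Broad peak calling

The caller tiles each genome in fixed windows and tests the ChIP midpoint
count in each window against `λ = max(depth-scaled Input count,
genome-wide ChIP mean per window)` with an upper-tail Poisson p-value,
Benjamini–Hochberg adjusted across windows; windows at `q ≤ 0.1` are
merged into broad peaks when separated by at most `gap` bp. The lenient
q-threshold is intentional: stringent thresholds fragment broad
heterochromatin domains. Function defaults are window 1 kb and gap 3 kb —
appropriate at real-genome domain scale, and used in the spiked-domain
recall test. The *pipeline* defaults are window 100 bp and gap 0: in the
compact synthetic genomes a silenced domain is a single TE of 120–450 bp
and neighbouring TEs are only a couple of hundred bp apart, so kilobase
windows would fuse distinct domains and make TE-level categories
unidentifiable. This scale choice is a property of the synthetic study
design, not of the caller.

Fragments enter windows by midpoint (each fragment counts once); region
counting afterwards uses the ≥ 1 bp fragment-span overlap rule, so a
fragment spanning two adjacent regions increments both.

# Orthologous regions and the count matrix

Per-individual peaks are filtered through reciprocal lifting, projected
into genome-A coordinates, and union-merged across all individuals of
both species. Genome A is the fixed merge coordinate system (the choice
is arbitrary for exact-inverse chains; it is exposed only through which
genome is called A). Merged regions are lifted once to genome B and must
pass the mappability filter in both species. Counting yields a region ×
individual matrix; regions with a nonzero count in strictly more than
half of all individuals (for 10 + 7 individuals: more than 8) are
retained — below that there is clearly no power to compare species.

# The NB differential engine

One negative binomial engine serves both ChIP region counts and RNA gene
counts (a single engine keeps the two analyses directly comparable; the
variance-modelling alternatives used for RNA in some pipelines are a
documented non-goal). Its parts:

* **Size factors** — median-of-ratios over features positive in every
  individual.
* **Dispersions** — per-feature method of moments `(var − μ)/μ²` on
  normalized counts, averaged over the two species and floored at 1e-8;
  a trend `α(μ) = a1/μ + a0` fitted by least squares; final dispersion
  `exp(w·log raw + (1 − w)·log trend)` with `w = 0.5`. The fixed
  geometric weight replaces empirical-Bayes machinery: at cohort sizes of
  7–10 per species the trend dominates noise in the raw estimates, and a
  fixed weight keeps the estimator monotone and transparent. `w` is
  exposed for sensitivity analysis.
* **Wald test** — per feature, IRLS for
  `log μ_ij = log s_j + β0 + β_sp x_j` (`x_j = 1` for species A),
  convergence at coefficient change `< 1e-8`, at most 50 iterations;
  non-converged or all-zero features are flagged `not_tested`. The SE
  from the Fisher information carries the small-sample factor
  `sqrt(n/(n − 2))` for the two estimated coefficients; without it the
  normal-approximation Wald test runs measurably above nominal at
  n = 16. The p-value is two-sided normal; no fold-change shrinkage.
* **Independent filtering** — base-mean quantile thresholds are scanned
  and BH applied to each surviving set; the threshold maximizing
  rejections at the working FDR wins (smallest on ties). This is an
  explicit stand-in for the cited package's filtering default and is
  documented as an approximation.
* **Classification** — `padj < 0.01` and positive/negative log2 fold
  change give `A_enriched`/`B_enriched`; everything else, *including
  untested features*, is `shared`, so category proportions are always
  over the full retained feature set.

# TE orthology and silencing calls

Orthologous TEs follow the four-step reciprocal construction: lift A
instances to B; keep those whose *lifted span* (the chosen reading of the
50 percent rule — measured against the lifted span, not the annotated
instance) is covered ≥ `min_bp_overlap = 0.5` by a same-name B instance,
ties resolved by largest overlap then smallest start; lift back and keep
survivors; repeat seeded from B; intersect the two pair sets, requiring
reciprocal overlap of at least half the shorter span in A coordinates.
Length and milliDiv of an orthologous pair are reported from the A
instance. Non-orthologous instances with a type name absent from the
other species' table are species-specific — the simulator emulates this
with private type names per species, the pattern of SVA_E/SVA_F being
annotated in only one genome.

A TE is *overlapping* when the union of orthologous regions covers at
least half its length in A coordinates, and it inherits the category of
the single region with the largest base overlap (ties to the smaller
region id). Inheriting from one region keeps the call interpretable when
regions disagree; aggregating counts across regions is a reasonable
alternative that was not made the default because it couples the TE call
to the occupancy filter in less obvious ways.

For the effect-size contrast of TE properties, "divergence below versus
above two-fold" is implemented as `|log2fc| < 1` versus `≥ 1`
(`lfc_split = 1`, configurable): the two-fold reading is the conservative
interpretation of an ambiguous wording, and the split point is exposed.
TSS distance is 0 for a TE overlapping a TSS and otherwise the gap
between nearest edges, so a TE ending one bp before a TSS is at
distance 1.

# Gene-level association

The TSS is the minimum `txStart` for plus-strand genes and the maximum
`txStart` for minus-strand genes — the literal txStart-based convention
(for a minus-strand gene the biological start would be an end
coordinate; the convention is kept symmetric and documented rather than
silently corrected). Upstream windows of 1/10/20/40 kb exclude the TSS
base and clip at chromosome ends. Per gene and window, the *distinct*
orthologous regions overlapping any TE in the window contribute their
counts once (two TEs under one region never double-count it); genes whose
window has no TE-overlapping region are excluded from differential
silencing. Expression is filtered by the "> 10/17 of individuals
nonzero" rule generalized as a ratio with the threshold rounded down
(17 → 10, 20 → 11), quantile normalized (ties averaged), and reported as
log2 CPM with pseudocount 1 — differential testing always runs on the
raw filtered counts.

The association report contains the per-silencing-category expression
divergence distributions with rank-sum contrasts, the DE-status
cross-tabulation with a chi-squared test, the Pearson correlation of
silencing versus expression log2 fold changes with a permutation p
(`(1 + #{|r*| ≥ |r|})/(n_perm + 1)`), and sign-consistency counts.

# The synthetic cohort generator

The generator is ancestor-based: one random ancestral genome, two
descendants evolved independently by per-base substitutions
(default 0.006 per lineage, about 1.2 percent pairwise divergence) and
Poisson indels (rate 2e-4/bp, geometric lengths of mean 3 bp). Because
both descendants carry exact coordinate maps to the ancestor, the A↔B
chains are computed by composition and are exact inverses — chain
symmetry holds by construction, not by approximation.

Defaults define the emulated study: 2 chromosomes × 1 Mb, 5000 TEs,
10 + 7 individuals, fragment length 200 bp (midpoints used for density),
NB dispersion 0.2, 30 expected ChIP fragments per silenced TE per
individual over a background of 5 fragments/kb, and a four-fold
(`species_effect_log2fc = 2`) enrichment difference for species-specific
silencing — applied *on top of* the shared baseline in the enriched
species, so a species-specific TE is enriched in both species but twice
log2-fold more in one. Per-class silencing priors are
SVA 0.30 > LTR 0.22 > LINE 0.12 > SINE 0.07 > DNA 0.05, with 80 percent
of silenced orthologous TEs silenced in both species
(`shared_fraction = 0.8`); single-genome TEs take the prior scaled by
0.6. milliDiv is drawn per class from truncated normals on [0, 400]
per-mil, with silenced instances drawn younger (mean scaled by 0.6) so
the divergence contrast between silenced and unsilenced TEs is
recoverable.

TE placement partitions each chromosome: class-dependent lengths
(LINE 300 / SINE 120 / LTR 220 / DNA 150 / SVA 450 bp around ~52 percent
repeat coverage) with random gaps and a 150 bp minimum spacer. The
spacer is a deliberate identifiability choice: without it, adjacent TEs
at this density end up under one merged H3K9me3 region and the
shared-versus-species-specific label of a TE becomes unknowable from
region-level data — the estimand itself would be confounded by
construction. Real repeat landscapes are more clustered; conclusions
about *nested or clustered* repeats do not transfer from these
simulations.

What else the generator does **not** emulate: TE consensus sequence (the
genomes are random, so annotations mark positions, not homologous
sequence), read-level error and alignment, non-autosomal chromosomes,
and copy-number variation between individuals. Tests passing on this
cohort therefore validate the interval logic, the statistics, and label
recovery — not robustness to alignment artefacts or repeat-internal
multi-mapping, which on real data are handled upstream and by the
mappability filter respectively.

Expression couples to silencing through `expression_coupling`: genes
with a species-specifically silenced TE within `coupling_window`
(default 10 kb) receive a true expression species effect of
`expression_coupling × direction`; all other genes draw from
`N(0, 0.15)` on the log2 scale. The default coupling of 0 makes the
association analysis a calibrated null — the configuration under which
the pipeline should, and in the acceptance checks does, find no
association.

# Problem sizes and determinism

The test suite simulates cohorts of 200 kb–1 Mb genomes with 200–5000
TEs and 4–17 individuals; the end-to-end acceptance check runs the full
default cohort (2 × 1 Mb, 5000 TEs, 10 + 7) once, and the association
calibration uses 100 gene-level replicates of 150 genes each. These
sizes were chosen so the whole suite exercises every stage at full
defaults while remaining comfortably desk-scale. All randomness flows
from a single integer seed per cohort (internally offset per stage), and
a fixed seed reproduces byte-identical FASTA, chain, BED and TSV
artifacts.

# Known limitations

* The peak caller is a single-scale Poisson window model: no local
  lambda at multiple scales, no duplicate marking, no input-free mode.
* Dispersion shrinkage is fixed-weight, not empirical Bayes; effect
  sizes are unshrunken, so low-count features show noisy log2 fold
  changes (mitigated by independent filtering).
* Mappability is exact-match; mismatch-tolerant mappability would score
  recently diverged duplications lower.
* The orthology procedure is name-exact: a TE re-annotated under a
  different subfamily name in the other species is non-orthologous by
  definition, as in the motivating analysis.
* `GRanges`-based coverage operations assume per-species coordinates fit
  in integers; genomes beyond ~2 Gb per chromosome are out of scope.
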