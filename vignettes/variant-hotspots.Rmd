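---
title: "Detecting non-random variant hotspots in single-cell bacterial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting non-random variant hotspots in single-cell bacterial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kakscan)
```

## The model and its assumptions

kakscan analyses substitution variants called from single-cell
whole-genome sequencing (SC-WGS) of a haploid bacterium observed under
several exposure conditions, with up to a handful of single-cell
replicates per condition. Three facts about SC-WGS drive the design:

1. **Whole-genome amplification creates spurious calls.** Artifacts
   arise independently in each amplified cell, so they are overwhelmingly
   replicate-unique. The concordance filter (`merge_replicates()`)
   retains a variant only when the *exact* call — identical
   `(contig, position, ref, alt)` — occurs in at least `min_support = 2`
   replicates of a condition. Identity includes the allele: the same
   position hit with a different base in another condition is tracked
   separately (`shared_positions()` vs `shared_variants()`).
2. **Genome recovery is partial and uneven.** Per-replicate depth
   tracks define, for every gene and condition, which positions were
   observable. Per-gene Ka/Ks uses only positions covered in at least
   `min_covered_replicates = 2` replicates — mirroring the merge rule,
   because only such positions could have yielded a retained variant.
3. **The genome is bacterial.** Genes are single-interval CDS (no
   introns), translated with NCBI genetic code 11. Overlapping genes are
   permitted by the data model (`gene_at()` returns all containing
   genes, and a variant inside an overlap is counted once per gene — a
   documented double-count at the Ka/Ks stage); the synthetic worlds are
   non-overlapping.

All internal coordinates are 1-based inclusive, the R/Bioconductor
convention; BED-like depth files (0-based half-open) are converted at
I/O only. Substitutions only: the upstream experimental context reports
no condition-dependent indels, so indels are rejected at ingest with a
warning rather than modeled. Multi-base substitutions form their own
class (`multi_bp`), tallied separately and excluded from Ka/Ks. An SNV
that creates or destroys a stop codon is non-synonymous (it changes the
encoded product); codons containing N are classed `unknown` and excluded
from Ka/Ks counts.

## Effect annotation from first principles

`classify_variants()` rebuilds the affected codon on the coding strand
(reverse-complementing for minus-strand genes), substitutes the
alternate allele, and translates both codons. This replaces a
third-party annotator with an implementation small enough to verify
exhaustively: the test suite enumerates all 64 codons x 3 offsets x 3
alternate bases (576 cases) against an independent full-gene-translation
oracle and requires 100% agreement.

## Ka/Ks: raw at genome scale, site-normalized per gene

Genome-wide Ka/Ks is the raw count ratio, because that is the convention
of published genome-wide tables and it is invariant to the gene
annotation. Per-gene ratios use Nei–Gojobori-style *site opportunity*:
each covered CDS position contributes the fraction of its three possible
substitutions that are synonymous to the synonymous site count and the
remainder to the non-synonymous count, so `syn_sites + nonsyn_sites`
equals the number of covered positions. Rates are `ka/nonsyn_sites` and
`ks/syn_sites`; the normalization does **not** cancel in the ratio
because the two site classes shrink differently as coverage drops.
Published per-gene tables are therefore not bit-reproduction targets —
the exact historical normalization is not recoverable — and the per-gene
machinery is validated by enumeration oracles and planted-truth recovery
instead.

One numerical convention was forced by the published numbers themselves:
the genome-wide table prints 64/117 as 0.54, 57/131 as 0.43 and 44/113
as 0.38. Those are *truncations* to two decimals (rounding would give
0.55, 0.44, 0.39). `trunc_decimals()` implements the reporting
convention; full precision is kept internally everywhere.

Gene-of-interest selection uses strict inequalities (`ratio < 0.2` for
synonymous-dense, `> 1` for non-synonymous-enriched, ties excluded) in
at least `min_conditions = 2` conditions with at least one variant.

## Null models

**Pascal probability.** "The probability of K shared variant positions
in a gene of length N" is read as `1 / choose(N, K)`: the chance that K
positions drawn uniformly without replacement coincide with K fixed
positions. N is the annotated gene length in bp (the codon-unit reading
was rejected as the less natural unit for positions). Computation is in
log space (`lchoose`); the tests verify against an exact big-integer
binomial built from limb arithmetic. Benjamini–Hochberg adjustment
across genes is reported alongside the raw probabilities as a clearly
labeled addition — the raw value remains the headline number.

**Continuum randomization.** The genome is concatenated into a continuum
of `total_length` positions; each iteration re-places every condition's
observed variant count uniformly with replacement at bp resolution
(collisions are allowed; their probability is negligible at genome
scale). The default statistic is the number of genes containing at
least one variant in every condition simultaneously; `max_gene_hits`
and the continuous `mean_gene_distance` are available, and any function
`(positions_by_condition, lookup) -> scalar` can be plugged in. The
empirical p-value `(1 + #{null >= obs}) / (iterations + 1)` never
reaches zero from a finite simulation. `p_combined` — the product over
conditions of each condition's empirical probability of hitting the full
observed shared-gene set — is an independence approximation reported
separately; it is how a "< 1e-8"-style figure can arise from a 1e6
iteration run, and it is never silently substituted for the empirical
p-value. Every result records its seed and iteration count.

*Calibration note.* The shared-gene statistic is lattice-valued, and
empirical p-values of a discrete statistic are super-uniform by
construction: their CDF touches the diagonal only at the support points.
A Kolmogorov–Smirnov uniformity test on such p-values measures the
statistic's discreteness, not the correctness of the randomization. The
calibration acceptance test therefore drives the machinery with the
continuous `mean_gene_distance` statistic, for which uniformity under
the null is the correct expectation (up to the 1/10^4 Monte Carlo
granularity).

**Friedman / Nemenyi / t.** The Friedman statistic uses the
tie-corrected chi-square form with average ranks, referred to chi-square
with k−1 df by default; `exact = TRUE` enumerates the `(k!)^n`
within-block permutation distribution (guarded at 1e6 combinations) for
small designs, where the chi-square approximation is known to be crude.
Nemenyi critical differences use studentized-range quantiles at infinite
df (`qtukey(...)/sqrt(2)`). The t-test is pooled-variance Student by
default with Welch behind a flag; degenerate zero-variance groups with
equal means return p = 1 rather than NaN.

## The synthetic world

`sim_config()` defaults state a scaled-down version of the study design
the package targets:

| parameter | default | why |
|---|---|---|
| conditions | Ground_UV, ISS_UV, ISS_Dark | three-exposure design |
| replicates_per_condition | 4 | four single cells per condition |
| genome | 2 contigs x 120 kb | multi-contig, scaled from ~7 Mb for test speed |
| n_genes / mean_gene_length | 120 / 900 bp | bacterial gene density and size |
| hotspot_genes x variants | 8 x 6 | eight genes of interest, modest burden |
| hotspot_nonsyn_fraction | 0.2 | synonymous-dense truth (Ka/Ks well below 1) |
| shared_across_conditions | 0.8 | most hotspot variants recur in all conditions |
| singleton_noise_rate | 50 /Mb/replicate | WGA artifact load the filter must remove |
| replicate_detection_prob | 0.9 | allele dropout in single cells |
| breadth_mean | 0.8 | partial genome recovery per cell |
| spectrum_weights | transitions 4:1 | A>G/G>A/C>T/T>C-dominated spectrum |
| mnv_rate | 0.05 | occasional adjacent 2-bp substitutions |
| contamination_fraction | 0.1 | off-target reads in classification tables |

Generated CDS start with ATG, end with a stop codon, and are internally
stop-free; genes are placed with >= 50 bp intergenic gaps on random
strands so intergenic analyses have support. Planted synonymous /
non-synonymous variants are drawn by enumerating a gene's substitutions
and sampling from the requested effect class, so ground-truth labels
come from the construction, independent of the annotator — the "label
honesty" tests then re-annotate every planted variant and require exact
agreement. Depth tracks use geometric covered/uncovered run lengths
around the requested breadth and are forced to cover each replicate's
own emitted calls (a replicate cannot call a variant it did not cover).
Noise is placed anywhere in the genome, never at a previously used
position, making replicate-unique artifacts exactly replicate-unique.

What the generator does **not** emulate: read-level error profiles,
alignment and calling biases, depth-dependent genotype quality,
contamination that reaches the variant calls, structural variation, and
real codon-usage or GC-content structure (intergenic sequence is
uniform-random). A green test therefore establishes that the pipeline's
logic is correct on data with the stated structure — not that any
particular biological dataset satisfies that structure.

## Numerical choices and degenerate inputs

* Thresholds are strict inequalities; ratio sentinels: `Inf` when
  `ks = 0 < ka` (flagged, not an exception), `NA` when a gene has no
  variants.
* A condition with fewer than 2 replicates yields an empty consensus and
  a loud warning, not an error (real designs have 1–4 cells).
* Contigs with no annotated genes return `NA` distances with a warning.
* Genes with zero covered positions are excluded from per-gene Ka/Ks and
  listed in an attribute.
* Duplicate calls within one replicate count once (warned); multi-allelic
  VCF records are split at ingest.
* All stochastic entry points take a `seed`; the run log is
  timestamp-free so identical configurations produce byte-identical
  output bundles.

## Acceptance-world design choices

The planted-recovery acceptance world (5 hotspot genes among 100 decoys,
5 variants each at non-synonymous fraction 0.2, detection 0.9, noise
50/Mb/replicate, 115 kb genome) was fixed analytically before running:
with ~25 variants per condition the expected null shared-gene count is
~0.6 against an observed 5, putting the target p-value orders of
magnitude under the 0.01 bound rather than at its edge. The calibration
world (200 kb, 170 genes, 30 variants per condition, 200 runs of 1e4
iterations) was likewise sized a priori for Kolmogorov–Smirnov power and
runtime.

## Known limitations

* The continuum null draws positions uniformly over the concatenated
  genome; per-contig constraints and local mutability covariates (GC,
  context) are not modeled — exactly as in the procedure it implements.
* `p_combined` assumes independence across conditions and should be read
  as an upper bound on surprise, not a calibrated p-value.
* Per-gene Ka/Ks uses count-based site opportunity, not a codon-model
  maximum-likelihood dN/dS; it is the right tool for sparse single-cell
  variant counts and the wrong one for divergent sequence comparisons.
* The Monte Carlo fast path assigns each position to at most one gene;
  with overlapping annotations it warns and truncates overlaps, and the
  slow custom-statistic path should be used instead if overlap-exact
  behavior matters.
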