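---
title: "Quantifying motif-disruption effects on TF binding with discriminatory SNPs"
author: "snpimpact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motif-disruption effects on TF binding with discriminatory SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpimpact)
```

## The idea

Two phenotypically matched cell lines that differ by fixed, homozygous
single-nucleotide variants are a natural mutagenesis screen: wherever one
line is homozygous for a variant and the other is homozygous reference (a
*discriminatory SNP*, discSNP), the two genomes present two alleles of the
same locus in otherwise comparable chromatin. If the discSNP falls inside a
transcription-factor motif, comparing normalized ChIP-seq (or DNase-seq)
signal between the lines measures — at base-pair resolution — how much that
particular base change costs the factor in occupancy.

`snpimpact` implements this framework end to end:

1. **Zygosity calling** from input ChIP-seq pileups (`call_zygosity`,
   `smooth_zygosity_blocks`, `find_disc_snps`).
2. **Motif-disruption scoring** of each discSNP against a PWM library
   (`analyze_disc_snp`, `call_disruptions`, `optimize_thresholds`).
3. **Impact statistics**: percent residual binding on the disrupted allele,
   grouped by motif, motif position, variant base, distance bin or peak
   class, with bootstrap CIs and permutation (maxT) correction
   (`percent_residual`, `group_impact`, `permutation_adjust`,
   `distance_bins`, `classify_peaks`).
4. **Contextual binding prediction**: a logistic-regression predictor of
   anchor-factor occupancy from the anchor motif score plus nearby
   contextual motif scores, validated against column-shuffled PWM controls
   (`build_training_sets`, `select_context_motifs`, `fit_predict_cv`,
   `compare_roc`, `sensitivity_at_fdr`).
5. **CRISPR deletion scanning**: wild-type-normalized IP/Input enrichment
   of deletion alleles from amplicon sequencing (`global_align`,
   `classify_allele`, `compute_enrichment`, `window_deletion_impact`).
6. **A synthetic-data generator** (`simulate_genome_pair` and friends)
   that produces every input with machine-readable ground truth.

## Zygosity model

A site's zygosity is decided from its total depth and variant read
fraction. Sites at depth ≤ 5 are ambiguous. Above that, fraction ≥ 0.9
calls a homozygous variant, ≤ 0.1 homozygous reference, 0.35–0.65
heterozygous; everything else stays ambiguous. The bands deliberately favor
precision over recall — a miscalled discSNP contaminates every downstream
allelic comparison, while a missed one merely shrinks the event set — and
they are exposed in `zygosity_thresholds()` because the depth/fraction
trade-off is a function of library depth.

Ambiguous calls are rescued by **block smoothing**: runs of consecutive
calls (same contig, gaps ≤ 50 kb) holding at least ten calls of which at
least 90% are homozygous variant have their ambiguous members reassigned to
homozygous variant. Segmentation is a greedy gap-based run construction
rather than a changepoint model: the contract (≥ 10 calls, ≥ 90% shared
zygosity) is what matters downstream, and the greedy rule is
dependency-free, deterministic and idempotent. Sites absent from one line's
table are assumed homozygous reference only when that line's pileup covers
them with ≥ 6 reads; otherwise the site is skipped — absence of evidence is
not evidence of the reference allele.

## Disruption scoring

PWMs are scored as log2 odds against a uniform background, the convention
under which the default thresholds are stated. Matrices are regularized
with a pseudocount of 0.001 and renormalized per column so consensus-only
matrices cannot produce infinite log-odds.

For each discSNP, a 40-bp window centered on the SNP (truncated at contig
ends) is scanned with every PWM over all placements, on both strands, that
contain the SNP. The chosen placement maximizes the **better** allele's
score, so the intact motif anchors the comparison and disruption is
measured as a loss relative to the best intact match; `Score_max` is that
better score and `DiffScore` the allelic difference at that same placement.
Placement ties on `Score_max` go to the larger `DiffScore`, then the `+`
strand, then the leftmost start; tie detection uses a 1e-9-bit tolerance so
that equal sums reached in different floating-point accumulation orders
still count as ties. A motif/SNP pair is called a disrupted site when
`Score_max ≥ 7.5` and `DiffScore ≥ 2.5` bits (`threshold_config()`).

`optimize_thresholds()` recovers such thresholds from data by a random
walk: each run initializes uniformly over the search box, proposes Gaussian
steps (sd 0.5 bits) and accepts a step only when the median percent signal
loss of called events improves on the current cross-validation fold;
thresholds calling fewer than 20 events are infeasible (−∞ objective).
Initialization is rejection-sampled into the feasible region — an
infeasible start has a −∞ objective everywhere within proposal reach and
could never accept a step. The reported thresholds are across-run medians,
and all walk parameters (steps, sd, bounds, minimum call count) are
arguments.

## Impact statistics

ChIP intensity is library-size-scaled to the mean library size, input
subtracted, and floored at zero; accessibility signal is additionally
quantile normalized (`limma::normalizeQuantiles`, tie-averaging). Percent
residual binding is `100 × disrupted / intact`; events whose intact-allele
intensity falls below 1 normalized unit are excluded, since a near-zero
denominator turns noise into arbitrarily large percentages. The alternative
"percent of the stronger allele" convention is available via
`percent_residual(denominator = "stronger")` for analyses framed as percent
signal loss.

Groups (by motif, motif position, variant base, distance bin or peak
class) with ≥ 5 events are summarized by the median residual, a 95% CI
from 1000 bootstrap medians, and a two-sided one-sample Wilcoxon
signed-rank test against 100%. Family-wise error across dependent group
tests is controlled by maxT permutation: group labels are permuted 1000
times preserving group sizes, each permutation records its smallest
Wilcoxon p, and a group's q value is the +1-smoothed fraction of null
minimum p values at or below its observed p. The +1 smoothing prevents
q = 0 from a finite permutation count. Inside the permutation loop the
Wilcoxon p is computed by an internal normal-approximation routine that
reproduces `wilcox.test(exact = FALSE, correct = TRUE)` (unit-tested for
equality) at a fraction of the cost.

Distance constraints on contextual disruptions use 10-bp bins sliding by
5 bp from 0 to 100 bp — exactly 20 bins, with distances measured
edge-to-edge (0 for overlapping motifs); an event may fall in two
overlapping bins, and the permutation correction runs across the 20 bins.

## Contextual prediction

Positive training sites are anchor-motif hits inside peaks; negatives are
hits outside peaks whose normalized IP read count in a 400-bp window does
not exceed the normalized input count, greedily matched 1:1 to positives by
Euclidean distance on the 20-dimensional mono+dinucleotide composition of
the hit ± 100 bp (without replacement). Peaks containing anchor-motif
discSNP disruptions are excluded from both classes. Contextual features are
the best log-odds score of each contextual PWM within 100 bp edge-to-edge
of the anchor, encoded 0 when nothing reaches the score floor — 0 is the
background log-odds, which keeps the model linear and means "no match".

Candidate contextual motifs must beat column-shuffled versions of
themselves — shuffling preserves length, composition and information
content while destroying positional structure — in more than 90% of
runs × shuffles before entering the final model. Models are plain
maximum-likelihood logistic regressions under stratified 10-fold
cross-validation; out-of-fold scores are pooled into one ROC per run and 10
runs redraw the folds. ROC curves are compared with DeLong's paired test on
the run-averaged scores. Negative sets are redrawn per selection run and
per final-model run alike, so selection and evaluation see the same
sampling variability.

## Deletion scanning

Merged amplicon reads are globally aligned to the wild-type sequence
(Needleman–Wunsch, affine gaps: a gap of length L costs 10 + 0.5 L, match
+5, mismatch −4 — the standard DNA scoring; the gap convention is stated so
results are reproducible bit-for-bit). Reads with ≤ 80% identity are
discarded; gap-free reads are wild type; reads with exactly one deletion
and no insertion are single-deletion alleles; everything else is discarded.
Enrichment of a deletion allele is `(IP_d / IP_WT) / (Input_d / Input_WT)`
per replicate, so the wild-type ratio is exactly 1 by construction and the
statistic is invariant to sequencing depth. Alleles with mean input counts
below 50 are flagged low-coverage and excluded from statistics; the
threshold is an argument because it depends on library depth. Effects of
1–2-bp deletions are localized with 2-bp windows sliding 1 bp, each
deletion entering every window it intersects, tested one-sided for
enrichment < 1.

## The synthetic generator, and what it does not emulate

The generator plants: equally spaced 200-bp peaks with a central summit
and one anchor-motif consensus instance; optional contextual motifs at
known edge-to-edge distances; discSNPs inside anchor motifs (maximally
disruptive base, carried by a randomly chosen line) and in background
sequence, spaced ≥ 1.5 kb by default so the isolated-SNP analyses apply.
Pileups are Poisson in depth with binomial sequencing error. IP counts are
negative binomial (dispersion 0.2 by default — ChIP counts are
overdispersed, and the real data's dispersion is not identifiable from
published summaries, so this is a modeling choice flagged in the
arguments; dispersion 0 gives the Poisson limit used by oracle checks)
with mean `lib × (input_base + base_intensity × Π effects)`, where the
multiplicative effects of motif disruption act only on the disrupted
line's allele and contextual effects are gated by an edge-to-edge distance
window. Input means carry no effect. Deletion libraries draw allele
abundances from a Gamma pool (wild type fixed at 30%), deletion lengths
Poisson around 26 bp, and IP reads proportional to abundance × retention.

Deliberately not emulated: read-level alignment artifacts, fragment-length
and shift effects, heterozygosity and allelic mapping bias, copy-number
structure, local GC/repeat biases, and correlated biological replicates.
Passing tests therefore demonstrate that the statistical machinery recovers
known truth under the stated noise model — not that the pipeline is robust
to every artifact of real sequencing data.

## Benchmark problem sizes

The packaged benchmarks run at: 2000 peaks × 100 replicates with 200
events per motif position and planted effects {1.0, 0.7, 0.5, 0.2}
(bootstrap-CI coverage of planted values); 200 null replicates of 10
groups × 50 events with 1000 permutations (family-wise error); 4000
labeled sites for the contextual predictor (with and without a planted
contextual effect); 10,000 pileup sites at depth 30 and 0.3% error
(calling precision and discSNP recovery); and exhaustive-enumeration
oracles for disruption scoring (500 windows) and affine alignment (reads
≤ 10 bp). These sizes make every experiment reproducible on a laptop while
keeping Monte-Carlo error well below the assertion margins. The
sequence-level path is cross-checked against the count-level shortcut on
one replicate per experiment (`check_sequence_pipeline`), where it must
reproduce the generator's bookkeeping exactly.

## Known limitations

* The zygosity bands stand in for depth-stratified cutoffs a production
  caller would learn from data; they are arguments, not constants.
* Log-odds thresholds (7.5/2.5 bits) are tied to the base-2,
  uniform-background scoring convention; rescale them if you change either.
* The deletion scanner analyzes substitution-free single-deletion alleles
  only; insertions and multi-edit alleles are discarded, as in the
  experimental design it supports.
* `delta_vs_expression` uses a binomial allele-count test as its
  differential-binding gate; it captures sampling noise but not biological
  replicate variance.
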