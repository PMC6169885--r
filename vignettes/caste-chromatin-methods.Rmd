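---
title: "Methods: windowed differential chromatin analysis for two-caste designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed differential chromatin analysis for two-caste designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(castechrom)
```

# The model

`castechrom` analyses ChIP-seq of histone modifications (H3K4me3, H3K27ac,
H3K36me3) in a two-condition design — queen vs worker honey bee larvae being
the motivating system — together with RNA-seq, CpG methylation and motif
data. The analysis unit is a sliding window: width 100 bp, spacing 50 bp, so
each interior window overlaps exactly two neighbours and differential
signals cannot fall between window boundaries.

## Enrichment over input

Reads (single-end, duplicates retained, mapping quality ≥ 20) are extended
to 250 bp from their 5′ end in the strand direction — a fragment-length
surrogate — and a read increments *every* window its extended interval
overlaps; with an overlapping tiling, multi-assignment is intended, so the
total of window counts exceeds the library size. Input coverage is counted
in the same windows expanded symmetrically to 5000 bp: the background rate
is a local average, stable where the 100-bp window count would be noisy.
Windows whose expansion crosses a contig edge are removed, and the removed
set is kept alongside the matrix so that rows + removed always equals the
grid size.

The enrichment of window *i* is the ratio of rate ratios

$$NC_i = \frac{C_i\,N_b}{C_b\,N_i},$$

which is invariant to rescaling all four quantities. Two numerical choices
matter here:

* **Width normalization (default on).** Applied to a raw expanded-window
  count, the equation pins an unenriched window at
  (window + extension − 1)/(5000 + extension − 1) ≈ 1/15 rather than 1,
  which would make a "threefold over input" rule unreachable even at strong
  peaks. `chip_enrichment()` therefore rescales the expanded input count to
  the window footprint before the equation, so background sits at ≈ 1 and
  enrichment reads in fold units; `width_normalize = FALSE` gives the
  literal raw-count ratio.
* **Zero input counts** are replaced by a pseudocount (0.5) so NC stays
  finite while the ordering of windows is preserved.

## Differential windows

With two replicates per condition, per-window variances are hopeless on
their own; they are shrunk toward a prior estimated from all windows of a
mark. Writing $s_g^2$ for the pooled residual variance on $d_g$ degrees of
freedom, the marginal model $s_g^2 \sim s_0^2 F(d_g, d_0)$ gives closed
moment equations on $z_g = \log s_g^2$: the excess of $\mathrm{var}(z)$
over $\psi'(d_g/2)$ identifies $d_0$ through the inverse trigamma, and the
corrected mean identifies $s_0^2$. When the observed spread does not exceed
the sampling contribution, $d_0 = \infty$ and $s_0^2$ is the mean variance
(the common-value limit). The moderated t uses the posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ on $d_0 + d_g$ degrees
of freedom.

The test runs on $\log_2(NC + 0.5)$ — a variance-stabilizing scale — while
the effect filter uses the raw-scale replicate-mean difference
$\Delta = \overline{NC}_W - \overline{NC}_Q$, because "threefold difference
in enrichment above input" reads as linear enrichment units. Both deltas are
reported. BH adjustment is per mark (three separate families, matching how
differential results are reported per modification). Windows with
$q \le 0.01$ and $|\Delta| > 3$ that overlap or abut with the same sign
merge into unique regions; direction ties cannot occur because the effect
filter excludes $\Delta = 0$.

## Genomic context

Distances are measured from region midpoints (symmetric, unlike nearest
edges) to transcript TSSs; multi-transcript genes contribute every TSS. The
sign follows transcription: negative = upstream, so minus-strand distances
flip. Equidistant ties go to the smaller gene identifier — deterministic.
A region is intergenic if it overlaps no gene span; otherwise exonic or
intronic by majority base, exon winning exact ties.

## Expression

Differential expression uses a Gaussian likelihood-ratio test on log2
abundance: full model (condition mean shift) vs reduced (grand mean),
statistic $n\ln(RSS_r/RSS_f)$. This keeps the full-vs-reduced structure of
bootstrap-based transcript DE tools while being computable from an
abundance matrix alone. One numerical point: at $n = 8$ the $\chi^2_1$
asymptotic reference is visibly anticonservative, so p-values are taken
from the exact monotone-equivalent $F(1, n-2)$ form of the same comparison;
the null is then exactly uniform and BH control holds at any replicate
number. The reported statistic remains the LR form.

Sample structure is summarized by classical (Torgerson) MDS on Euclidean
distances of log2 abundance; orientation is arbitrary. Chromatin-expression
coupling is measured by Spearman's ρ between the signed region Δ and the
gene's expression log fold change, per mark, over all (region, gene)
span-overlap pairs; pairs below three are flagged rather than tested. The
mark-combination analysis compares each combination's gene expression to a
single equal-size random background draw (seed-controlled) with a two-sided
Wilcoxon rank-sum test — the background construction mirrors comparing
marked gene sets "to a random sampling of genes" — with BH across the
combinations.

## Methylation and permutation tests

Per-CpG differential methylation is Fisher's exact test on methylated vs
unmethylated counts between conditions, BH < 0.05, excluding sites with
zero coverage in either condition. Two permutation constructions measure
enrichment:

* **Point features in regions** (DMPs × differential mark regions):
  observed = features inside regions; the null relocates each region
  uniformly within its own contig, preserving lengths — conditioning on the
  observed region-length distribution. A feature-shuffling null is provided
  as an option; outputs label which scheme produced them.
* **Gene sets × peak-bearing genes** (DE genes × intronic H3K27ac):
  observed = intersection size; the null redraws equal-size gene sets
  without replacement, 1000 times by default.

Empirical p-values carry a +1 pseudocount, $(1+k)/(1+B)$: never zero,
bottoming out at 1/1001 for 1000 permutations — the natural reporting floor
"p < 0.001". Fold enrichment is observed over null mean.

## Motifs

Peaks are replaced by 5-kb windows centered on their midpoints (peaks too
close to a contig edge are dropped and counted). A PWM — zero probabilities
floored at $10^{-3}$ and renormalized, so log-odds stay finite — is scanned
at every offset on both strands; the best site per window is kept if it
scores ≥ 0 bits, with ties broken toward the smallest |offset| then the +
strand, using a numerical tolerance so summation order cannot decide ties.
Central enrichment tests, for each half-width in
{50, 100, 250, 500, 1000, 2450} bp, whether best sites concentrate within
± that half-width more than uniform placement allows (binomial, success
probability = central positions / possible positions), reporting the best
window after Bonferroni correction for the ladder — a ladder approximation
to a full sweep, stated in the output. The motif probability curve bins best
sites by signed offset; its mass equals the fraction of windows with a hit
(hit-less windows stay in the denominator).

# The synthetic generator

The generator's job is to produce data with exactly the statistical
structure the analysis assumes, plus a truth table, so recovery can be
scored. Defaults describe one fixed miniature study, chosen once:

| parameter | default | rationale |
|---|---|---|
| genome | 2 contigs × 150 kb | large enough for ~5800 windows and 40 spread-out spike regions |
| genes | 40 × (3 exons of 200 bp, introns 500 bp) | ~21% genic fraction, so gene-body enrichment can clear threefold after composition effects |
| ChIP replicates | 2 per caste | the replicate design of the emulated studies |
| RNA-seq replicates | 4 per caste | likewise |
| library | 150 000 reads/sample (~0.5 background reads/bp) | window counts ~100–200: Poisson noise small against a Δ > 3 filter |
| input depth | = ChIP depth | the relative input depth is genuinely unstated in such designs; exposed as a free parameter |
| TSS enrichment | 6-fold | typical promoter-mark metagene amplitude |
| gene-body enrichment | 3.5-fold | attainable given the genic fraction (the composition ceiling is genome/genic ≈ 4.7) |
| spikes | 20 per condition, fold 8, width 600 bp | the recovery condition the acceptance checks exercise |
| expression effect | 2 log2 units at per-transcript SDs drawn from a scaled inverse-χ² (d0 = 10, s0² = 0.09) | recoverable at n = 4 and leaves a recoverable variance prior |
| DMPs | 5% of 2000 CpGs at proportions 0.8 vs 0.1, coverage ~30 | unambiguous Fisher calls at realistic depth |

Two calibration details are deliberate. First, feature read fractions are
solved analytically from the target enrichment: the TSS Gaussian
(fragment-center SD 150 bp) is integrated over the counting footprint and
the division by total library size (which itself contains the feature
reads) is accounted for, so the *realized* window enrichment at a TSS
matches the configured fold. Second, spike reads are drawn at rate
(fold − 1) × library/genome, so the planted difference measured on the
enrichment scale is fold − 1 regardless of composition. H3K27ac spikes are
placed inside introns — the candidate enhancer signature — and the
expression generator couples genes overlapping spiked marks to a
caste-consistent boost, which is what makes the chromatin–expression
correlation recoverable rather than assumed. Planted DMPs can be
concentrated inside supplied regions (the pipeline uses the H3K36me3
spikes), producing the DMP × mark permutation enrichment.

A fast mode (`generate_window_counts()`) emits Poisson window counts from
the same intensity model directly, skipping reads; it idealizes background
at exactly NC = 1 and is used where many independent runs are needed (null
false-discovery calibration).

What the generator does *not* emulate: fragment-size distributions, PCR
duplicates, mappability and GC bias, overdispersion beyond an optional
gamma mixing, genuine transcript quantification noise from pseudoalignment,
spatial autocorrelation of methylation. Passing recovery tests on this
generator therefore demonstrates correctness of the inferential machinery
under its stated assumptions, not robustness to those artefacts in real
libraries.

## Determinism

One master seed governs everything; each stage derives its own stream by
hashing the stage name onto the seed, so adding a stage never perturbs
another's draws. `run_synthetic()` writes all inputs and outputs in
standard text formats plus a manifest of md5 checksums, and repeated runs
with the same configuration are byte-identical — the manifest deliberately
records no timestamps.

## Problem sizes

The test suite and the acceptance script run everything at the default
study scale (~5800 windows × 14 samples, 40 genes/transcripts, 2000 CpGs
per study; 1000-round permutations; 10–20 independent runs for calibration
checks), which keeps a full run on one CPU in the low minutes while leaving
all statistical claims testable at their stated tolerances.

# Known limitations

* The enrichment scale depends on the width-normalization convention
  (documented above); raw-ratio users must rescale the threefold rules.
* The moderated-t machinery assumes exchangeable windows within a mark; a
  mean-variance trend (a spline prior) is out of scope.
* The Gaussian LRT ignores quantification uncertainty per transcript; with
  real bootstrap data a variance decomposition would be preferable.
* The relocation null for region overlap conditions on contig assignment
  and lengths only; segmentation-aware nulls (GC, mappability strata) are
  out of scope.
* The central-enrichment ladder is a coarse approximation of a full
  half-width sweep; with very diffuse central signals the Bonferroni factor
  can cost sensitivity.
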