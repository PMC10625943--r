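---
title: "Methods: integrative two-tissue multi-omics classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative two-tissue multi-omics classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the tunable parameters, the numerical
choices, and the design decisions behind `tissuedom`, and states what the
synthetic validation does and does not demonstrate about real data.

## The classification procedure

The pipeline classifies genes and proteins measured in two tissues (called
`liver` and `muscle` throughout, but any pair of names works) in seven
stages.

**Gene models and TSS windows.** Transcripts are read from GTF (Ensembl
dialect) or BED12; coordinates are converted once at the I/O boundary to
0-based half-open intervals and all internal arithmetic stays in that
system. Transcripts sharing (chromosome, strand, TSS) are merged into one
unit; a merged unit's expression is the sum of its members' counts/TPM
(configurable to `max`), because summation preserves total signal at that
start site. The analysis window is the strand-aware half-open interval
`[TSS − 200, TSS + 400)`; on the minus strand this is the mirrored
interval `[tss − 400 + 1, tss + 200 + 1)` in genomic coordinates, which has
the same length (600 bp) and contains the TSS base. The promoter used for
region-level summaries is `[TSS − 1500, TSS)`, excluding the TSS base; the
length is configurable since the underlying definition is conventional.

**Window methylation, Otsu, Silverman.** Per-CpG methylation ratios pool
replicates (`sum meth / sum total`) and require a minimum pooled coverage
(default 5 reads per tissue; the default exists to keep coverage-1 sites
from contributing 0/1 ratios, and is configurable). Window methylation is
the mean of per-CpG pooled ratios. The hypo/hyper threshold is computed by
Otsu's method on the *pooled* two-tissue sample of window ratios (one
global threshold, matching the single cutoff drawn across both tissues'
distributions); the implementation evaluates the exact between-class
variance at every midpoint of consecutive sorted unique values rather than
on a 256-bin histogram, which makes it deterministic and lets tests compare
it to a brute-force oracle exactly. Ties break toward the smaller
threshold, and a ratio exactly at the threshold classifies as *hyper*
(an arbitrary but fixed boundary rule). Bimodality is assessed with the
Silverman bootstrap test: the critical bandwidth is the smallest Gaussian
KDE bandwidth giving at most *k* modes (bisection, 30 iterations; mode
counting on a 512-point grid over the data range ± 3 bandwidths), and the
p-value is the fraction of variance-rescaled smoothed-bootstrap resamples
showing more than *k* modes at that bandwidth.

**Differential methylation.** Each CpG is tested with a beta-binomial
likelihood-ratio test on replicate-level counts: H0 one shared methylation
mean, H1 tissue-specific means, with a shared precision profiled on a fixed
grid under H1. The statistic is referred to chi-square(1) after a
genomic-control rescaling: with three replicates per tissue the raw LRT is
tail-inflated (about five-fold at p = 10^-3 in null simulations), and
dividing by the ratio of the median statistic to the chi-square(1) median
restores near-uniform null p-values (Kolmogorov-Smirnov distance below
0.01 in the package's null simulations). The factor is only estimated when
at least 200 sites are tested; strong differential sites barely move the
median, so the rescaling is driven by the null bulk. With a single
replicate per tissue the test falls back to Fisher's exact test on pooled
counts. DMCpGs are sites with Storey *q* < 0.01 (q-values computed over
tested sites only). A gene is a DMG for a tissue when it is hypomethylated
in at least one tissue, has at least one DMCpG with that tissue's
hypomethylation direction inside the window, and shows a consistent
window-mean difference; the consistency condition resolves genes whose
window contains DMCpGs of both directions (those are flagged as conflicts
rather than labelled).

**Differential expression.** Genes must have positive counts in at least 6
of 11 replicates in one tissue ("present" is interpreted as count > 0; a
CPM floor would be a plausible alternative but is not adopted). The test is
an in-repo negative-binomial two-group comparison: median-of-ratios size
factors, tagwise method-of-moments dispersions shrunk toward a fitted
`a + b/mu` trend (prior weight 20 pseudo-degrees of freedom), a
likelihood-ratio statistic against chi-square(1), and BH q-values, with
labels at *q* < 0.01 by fold-change sign. Parity with dedicated count
packages is claimed at the level of operating characteristics — the test
suite checks null calibration, power on 4-fold effects, and per-gene call
agreement with an established NB implementation on a planted fixture — not
per-gene p-value identity. Log2 fold-changes are reported with a 0.5
pseudo-count so they stay finite; the test itself uses raw counts.

**Proteome.** Detection requires intensities in ≥ 3 of 5 replicates.
Intensities of both-tissue proteins are transformed with
`h(x) = γ·arcsinh(a + b·x)`; `(a, b)` maximize the transformation profile
likelihood (Gaussian residuals around per-protein-per-tissue means plus
the Jacobian term), with least-trimmed-squares robustness (the worst 10%
of proteins by mean squared residual are excluded and the fit repeated
until stable). Because the likelihood only identifies `γ` jointly with the
residual scale, the package fixes the transformed error variance at 1 and
sets `γ` to the reciprocal residual standard deviation; `γ` is then a real,
recoverable parameter, which the tests exploit. Means are compared with an
empirical-Bayes moderated *t*: prior variance and prior degrees of freedom
are moment-matched on the log sample variances, and `d0 = 0` reduces the
statistic exactly to the ordinary pooled *t*. Proteins detected in only one
tissue are DEPs without a test, as the detection rule already encodes the
evidence. Missing intensities are never imputed.

**Protein/mRNA ratios and DRPs.** The per-tissue ratio is
`log(mean intensity / mean TPM)`, defined only where the protein is
detected and TPM > 0. Although the source convention is phrased as a ratio
of expression to abundance, the quantity is treated as the protein/mRNA
ratio throughout, with a flag to flip: the deviation calls are invariant
under a global flip, only the direction labels swap. The first tissue's
ratio is regressed on the second's (ordinary least squares); protein *i* is
flagged when the MSE of the line refit without *i*, evaluated on the
remaining *n* − 1 points, is strictly below the full-fit MSE
(`MSE_full = SS/n`). Analytically this flags points with
`r_i^2/(1 − h_i) > MSE_full`, i.e. |standardized residual| ≳ 1, so on pure
Gaussian scatter the rule flags about 32% of points — its selectivity comes
entirely from genuine outliers inflating the MSE. The alternative reading
(comparing against the refit evaluated on all *n* points) is available
behind a flag, but is provably never satisfied for OLS (the full fit
minimizes SS on all points), which supports the default reading. Flagging
is one-pass, not iterative.

**TF binding and DTGs.** Binding uses strand-agnostic
`[TSS − 1000, TSS + 1000)` flanks. Two Welch-test families run within each
tissue on `log2(TPM + 1)` (log stabilizes variance across the expression
range; raw TPM is available): per-TF marginal tests (bound vs unbound) and
pairwise tests between binding states observed as a cross-tissue
difference. All p-values share one Storey correction. A gene with differing
states is a DTG directly when its state pair is significant, or by
combination inference when its state difference decomposes into
individually significant TFs. Both families are emitted for inspection
because the compressed published description does not pin down the exact
family; this is the most direct executable reading.

**Integration.** Transcript- and protein-level calls are collapsed to gene
level; genes whose members disagree in direction are flagged `conflict`
and excluded from directional overlaps. Composites require direction
consistency at every level (DM-DEG: DMG ∩ DEG same tissue; DM-DEP: DM-DEG
∩ DEP; DR-DEP: DRP ∩ DEP; DT-DEP: DTG ∩ DEG ∩ DEP), with cross-direction
overlaps tested separately as depletions. Enrichment uses right-tailed
Fisher tests against the background of all measured genes or proteins at
the relevant level, BH-corrected across sets.

## The synthetic study

The generator (`sim_config()`, `simulate_study()`) emulates the
statistical structure the pipeline assumes; its defaults are the package's
canonical validation conditions and are chosen once:

- 2,000 genes on 4 chromosomes (200 for the tiny fixture), one gene per
  6-kb slot so the −1500..+2000 scan flanks never overlap neighbours; 5%
  of genes carry a second transcript sharing the TSS to exercise merging.
- Methylation: 10% + 10% planted DMGs at hypo/hyper means 0.10/0.80
  (Δ ≈ 0.7); beta-binomial counts via `Beta(μs, (1−μ)s)` with
  `s = 1/0.02 = 50`, Poisson coverage of mean 30, 3 replicates per tissue.
  Genes with concordant states share one planted ratio across tissues, so
  they are exact nulls for the differential test. Window CpG counts come
  from two density classes (Poisson means 10 and 47); 85% of DMGs are
  low-density. Non-CpG (CHG/CHH) sites are emitted at ratio 0.02.
- Expression: baseline log2 TPM ~ N(5, 1); hypomethylation adds a +2 log2
  boost in the hypomethylated tissue — for DMGs with probability 0.8 only,
  so methylation-expression coupling (and hence the DM-DEG overlap) is
  deliberately partial; independent DEGs (10% of non-DMGs) and TF-bound
  genes add further shifts. Negative-binomial counts with dispersion
  0.025 (biological coefficient of variation ~16%, representative of
  isogenic-mouse replicates), 11 replicates.
- Proteome: log intensity = α + β·log(planted mRNA) + a per-protein
  translation-efficiency offset shared by both tissues (SD 1.0 on the
  natural-log scale — protein/mRNA ratios in real data span orders of
  magnitude, and a narrower spread lets planted outliers attenuate the
  DRP regression slope, leaking the shared offset into every residual) +
  ln 3 for planted DRPs (5% per tissue) + replicate noise of SD 0.15
  (≈ 15% CV, typical for label-free intensities); 5% random dropout and a
  5% tissue-absent subset; 5 replicates.
- Peaks: TF binding itself carries the expression effect (bound in a
  tissue ⇒ +2 log2 there), so background genes bound in both tissues are
  expression-balanced non-DTGs while the 6% of genes bound in one tissue
  only are DTGs and DEGs; ATAC peaks cover hypomethylated genes with
  probability 0.9 vs 0.2; two consistent source files per histone mark per
  tissue; CpG islands cover high-density genes with probability 0.9.

What passing the recovery tests shows: the pipeline's calls are correct
when the data follow the generating model at realistic noise levels, the
tests are calibrated on exact nulls, and the structural analyses localize
planted signal. What it does not show: robustness to spatially
autocorrelated methylation domains, abundance-dependent protein
missingness, isoform-level effects, batch structure, or annotation error —
none of which the generator emulates (read-level simulation and enhancer
geometry are out of scope by design).

## Numerical choices and problem sizes

- All q-value cutoffs default to 0.01 and Fisher significance to 0.001,
  the canonical values for this analysis; every one is a parameter.
- Storey's π0 uses the cubic-smoother estimate on λ = 0.05..0.95
  extrapolated to λ = 1, with a fixed λ = 0.5 fallback below 100 p-values
  where the smoother is unstable; π0 is clamped to [1/n, 1].
- The beta-binomial precision grid is {2, 5, 10, 20, 50, 100, 300, 1000,
  1e5}, spanning strongly overdispersed to essentially binomial counts.
- The NB mean optimizations use Brent's method on the log scale with a
  ±4-unit bracket around the moment estimate.
- `vsn_fit` optimizes (a, log b) by Nelder-Mead on the profile objective
  (relative tolerance 1e-10, 500 iterations) inside up to 10 trimming
  iterations.
- Ward clustering is agglomerative variance-minimizing linkage on
  Euclidean distances (`ward.D2`), cut at k = 2 for the density classes;
  the merge order is oracle-checked against exhaustive ΔSS search.
- The test suite validates calibration on 20 seeds per test with 600-1,500
  null features each, and structural recovery on 20 seeds of 250-gene
  studies; the full-recovery run uses one 2,000-gene bundle. These sizes
  are the package's validation conditions; all scale linearly if enlarged.

## Known limitations

- The DMCpG genomic-control factor assumes most tested sites are null;
  on data where a majority of CpGs are differential it becomes
  conservative.
- The DRP rule is intrinsically threshold-free; on outlier-free data it
  flags ~32% of points by construction. Interpret DRP calls jointly with
  the regression summary (slope, MSE) that `call_drps()` attaches.
- Merged-TSS units inherit the representative transcript's ID; analyses
  that need member-resolution must keep the `members` column.
- The combination-inference DTG rule treats marginal TF significance in
  either tissue as sufficient; with many TFs this is permissive, matching
  the inclusive published definition rather than a conservative variant.
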