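---
title: "Models and methods behind methlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methlink)
```

# Scope

`methlink` implements an integrated analysis of how a short-term
cytokinin (6-benzylaminopurine, 6-BA) treatment reshapes a plant
methylome and its downstream regulatory layers: per-cytosine methylation
quantification, sliding-window DMR calling, allele-specific expression
(ASE), 24-nt siRNA cluster calling, FPKM-based differential expression,
DMR–element annotation, and kinship-aware SNP–trait association with
additive/dominance decomposition. Because the real sequencing libraries
behind such a study are far beyond desk scale, every stage is paired
with a synthetic-data generator that plants known effects, and the test
suite validates each stage by parameter recovery.

This vignette records the models, the defaults and why they were
chosen, the numerical choices, and the known limitations. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

# Methylation quantification

For a cytosine with `mC` methylated and `umC` unmethylated reads, the
methylation level is `ML = mC / (mC + umC)`. Bisulfite conversion is
imperfect: with conversion rate `c`, an unmethylated cytosine escapes
conversion and reads as methylated with probability `r = 1 - c`. The
corrected level is

```
ML_corrected = (ML - r) / (1 - r),  clamped to [0, 1].
```

A point that merits emphasis: this formula maps observed levels into
`[0, 1]` only when `r` is the *non-conversion error rate*, not the
conversion rate itself (with `c ≈ 0.995` the formula would be negative
almost everywhere). `methlink` therefore takes `r` as the error rate
throughout and `sim_config()` accepts the conversion rate `c`,
internally using `r = 1 - c`. Under the error model used by the
simulator — 5mC is never converted, unmethylated C escapes conversion
with probability `r` — the observed level has expectation
`pi + (1 - pi) * r`, and the correction is exactly unbiased for the true
level `pi`. Sampling noise can push `ML` below `r`, hence the clamp.

Whether a site is *genuinely* methylated is decided by a one-sided
upper-tail binomial test of `mC` in `mC + umC` trials against the null
success probability `r` (`call_methylated_site()`), at `alpha = 0.05`
and a coverage floor of 5 reads. Sites below the floor are excluded, not
called unmethylated: absence of evidence at low coverage is not evidence
of absence. Because the binomial test is exact, its type-I error is at
most nominal; the suite verifies ≤ 5% empirically on 10^4 pure-noise
sites.

Sequence context (CG / CHG / CHH, H ∈ {A, C, T}) is read off the
reference strand-awarely; minus-strand cytosines are evaluated on the
reverse complement. Sites whose trinucleotide window runs past a
chromosome end are excluded with a warning rather than given a
fabricated context.

## Allelic methylation genotyping

For CpG loci the methylation support rate
`S = mC_reads / (mC_reads + C_reads)` runs from 0 (neither allele
methylated) through 0.5 (typical of one methylated allele) to 1 (both
alleles methylated). A locus changes its allelic methylation state
between conditions when `|S_treat - S_ctrl| / S_ctrl > 0.5` (strict).
When `S_ctrl = 0` and `S_treat > 0` the relative change is reported as
`Inf` and the locus is classified as changed — any gain from zero is an
obvious change; `S_ctrl = S_treat = 0` is unchanged.

# DMR calling

DMRs are found in four deterministic steps
(`enumerate_windows() |> window_test() |> merge_significant() |>
region_filter()`, composed by `call_dmrs()`):

1. **Windows.** 1000-bp windows advanced in 100-bp steps. Counts are
   pooled per group over *eligible* sites — pooled coverage ≥ 5 in
   *both* groups. The symmetric eligibility rule keeps the downstream
   per-site ANOVA comparing the same site set in the two groups. The
   implementation aggregates per 100-bp bin and takes rolling sums,
   which the tests prove identical to brute-force enumeration.
2. **Window test.** Two-sided Fisher exact test on the pooled 2×2 table
   `[[mC_ctrl, umC_ctrl], [mC_treat, umC_treat]]`. The p-values use the
   minimum-likelihood two-sided rule, matching `stats::fisher.test` to
   numerical precision while being vectorised for genome-scale scans.
   Pooling across a window trades context- and replicate-resolution for
   coverage robustness; context-stratified calling is a non-goal.
3. **Merging.** Windows with `p < 0.05` are merged when they overlap or
   abut (gap 0); windows separated by an unmerged step stay distinct.
   Merged regions are pairwise disjoint and span the union of their
   members.
4. **Region confirmation.** One-way two-group ANOVA on per-site
   corrected methylation levels (replicates pooled within group per
   site); regions are retained at `p < 0.05` and labelled hyper/hypo by
   the sign of the pooled treated-minus-control difference. The sums of
   squares are computed directly, so zero within-group variance yields
   `p = 0` (retained) for separated groups and `p = 1` (rejected) for
   identical groups; for two groups the F statistic equals the squared
   pooled-variance t statistic, which the suite checks numerically.

No multiple-testing correction is applied inside DMR calling: the
procedure mirrors a candidate-screening design in which raw `p < 0.05`
windows and regions are "candidate DMRs". Users wanting genome-wide
error control should treat the output as a candidate set.

Called region boundaries are window unions, so a planted DMR is
recovered with up to ~900 bp of slack per side. For recovery
benchmarks the generator plants 3-kb DMRs: at that size a 50% reciprocal
overlap criterion measures detection rather than boundary resolution
(a perfectly detected 2-kb DMR inside a 3.8-kb called region sits right
at the 0.53 boundary).

# Allele-specific expression

Variants enter ASE analysis when they are biallelic SNVs with phred
quality ≥ 20 that do not belong to any run of ≥ 3 SNPs spanning ≤ 35
bases (the whole run is removed; runs are evaluated on all input SNVs).
A locus must also carry total allelic depth > 5 in both conditions.

ASE is quantified as the allele fraction `ALT / (ALT + REF)`; the
complementary ratio `A/R = ALT / REF` is reported for distributional
summaries. Differential ASE between conditions is a two-sided Fisher
exact test on condition-level REF/ALT counts with replicates summed —
the paper-scale analysis reports condition-level ASE, and a
replicate-variance-aware (beta-binomial) test is a declared non-goal.
Significance is `p < 0.05` unadjusted.

Heterozygosity for genotype-transition classes (het–het, het–hom,
hom–het, other) uses a configurable rule: minor allele with ≥ 2 reads
and frequency ≥ 0.1. Genes are represented by the locus within their 3′
UTR or within 500 bp beyond its outer boundary (strand-aware) carrying
the maximum total supporting reads, ties broken to the smallest
coordinate for determinism.

# 24-nt siRNA clusters

Cluster calling approximates island-based callers with a gap-linking
rule: maximal chains of 24-bp reads with inter-read gaps ≤ 75 bp,
retained at ≥ 10 reads. Clusters separated by ≤ 150 bp (inclusive) are
merged into siRNA loci; merging is idempotent. Expression is RPM
(`count × 10^6 / library_total`). Differential loci combine
`|log2 fc| ≥ 1` on RPM with a 1-RPM pseudocount and a Fisher exact test
of locus count versus the library remainder, `p < 0.05`. The
pseudocount keeps fully silenced loci representable — necessary when
nearly all significant loci are downregulated, as in the motivating
study. TE overlap is ≥ 1 bp intersection under half-open coordinates,
summarised within genic vs intergenic strata.

# Differential expression

FPKM is `fragments × 10^9 / (length_bp × total_fragments)`. A feature
is differentially expressed only when all three criteria hold:
`|log2 fc| ≥ 1` on group-mean FPKM, Fisher exact `p < 0.05` on pooled
fragment counts against library remainders, and FPKM strictly greater
than 5 in **every** sample (read per replicate — the strictest
defensible reading). lncRNAs pass the stable-expression filter when
group-level FPKM exceeds 1 in one group and 0 in the other.

# DMR annotation

Features count as "within" a DMR at ≥ 1 bp overlap (half-open),
because partially overlapping elements are biologically meaningful at
region boundaries. Element classes are derived from the multiset of
overlapping gene/lncRNA/siRNA features (`single_gene`,
`gene_plus_siRNA`, …); TE overlaps are recorded but do not enter the
class. Interval work is delegated to `GenomicRanges`; the suite keeps an
independent quadratic oracle. Meta-feature methylation profiles use 10
bins per 2-kb flank and 20 body bins, coverage-weighted and
strand-oriented.

# SNP–trait association

SNPs are filtered at MAF ≥ 0.05, missingness ≤ 0.25, and ≥ 3
individuals in each minor-allele-carrying genotype class. The mixed
model is

```
y = mu + Q beta + x_add a* + x_het d* + u + e,   cov(u) = sigma_g^2 K
```

with `K` either supplied or built as a VanRaden genomic relationship
matrix from the genotypes (missing values mean-imputed for `K`,
casewise-deleted for per-SNP tests). The variance ratio
`delta = sigma_e^2 / sigma_g^2` is estimated per SNP by profile REML on
the eigenbasis of `K` (one-dimensional optimisation over
`log delta ∈ [log 1e-5, log 1e5]`); SNP significance is an F-test of
the joint additive + heterozygote terms at the REML optimum, and `R^2`
is the share of covariate-adjusted sum of squares explained by the SNP
terms on the whitened scale. With `K = I` all eigenvalues are equal, so
the weighted fit is OLS for any `delta` and the test reduces exactly to
the ordinary F-test — a limit the suite checks to 10^-6.

Effects are decomposed from genotype-class means:
`a = (m2 - m0)/2` (half the homozygote difference, oriented so the
major-allele homozygote is the reference class) and
`d = m1 - (m0 + m2)/2` (heterozygote deviation from the homozygote
midpoint). A locus is a *prominent dominant-effect locus* when
`|d|/|a| > 2` strictly; `d/a = 2` exactly is not prominent, and `a = 0`
yields an infinite sentinel (prominent iff `|d| > 0`). Multiple testing
uses Storey-style q-values in the conservative λ = 0 variant — i.e.
Benjamini–Hochberg — with joint significance `p < 0.001` and
`q < 0.10`.

Two design notes on the simulation studies:

* **Dominance control.** The "pure-additive loci are rarely flagged
  prominent" property is evaluated over causal additive loci whose
  effects are detectable at the stated sample size (20 loci, `a = 0.75`,
  residual SD 1, `n = 500`, replicated populations). For *null* loci the
  ratio `|d̂|/|â|` is a ratio of two near-zero estimates and is flagged
  ~30% of the time regardless of implementation quality — which is why,
  as in the motivating analysis, the classifier is only meaningful for
  loci that show an association in the first place.
* **Recovery precision.** At `n = 500` and residual SD 1 the standard
  error of `d̂` is at best ~0.09 (balanced classes), so single-replicate
  recovery within ±0.15 holds in roughly 90% of replicates, not always.
  The suite therefore asserts unbiased mean recovery across replicates
  plus a per-replicate coverage floor of 80%, and the acceptance script
  reports mean recovered effects over 60 replicate populations.

# The synthetic-data generators

`sim_config()` holds every parameter; each generator draws from its own
seed-derived RNG stream, so outputs are byte-identical given a seed and
independent of call order. Defaults describe the emulated study
conditions: 3 biological replicates per group, Poisson coverage with
mean 30, conversion rate 0.995, baseline methylation 0.40/0.20/0.10 in
CG/CHG/CHH (a typical plant leaf ordering), genomes at GC 0.34.

* **Genome**: i.i.d. bases at the configured GC fraction. No repeats,
  no isochores.
* **Methylome**: per-context baseline levels; planted DMRs shift the
  treated group by `delta_ML` (validated to stay in `[0, 1]`);
  methylated reads are never converted, unmethylated reads escape
  conversion with probability `1 - c`. Coverage is Poisson and
  low-coverage sites are still emitted — filtering is the caller's job.
* **Allelic counts**: `Binomial(depth, f_condition)` ALT counts per
  replicate.
* **siRNA reads**: exactly 24 bp, uniform within their planted
  cluster, plus optional uniform background.
* **Population**: Hardy–Weinberg genotypes at uniform MAFs,
  missing-completely-at-random genotypes, phenotype = planted additive +
  dominance effects + polygenic term with VanRaden-GRM covariance built
  from the simulated genotypes themselves + Gaussian residual.

What the generators do *not* emulate — and hence what passing tests do
not show about real data: read-level error and mapping bias (inputs are
already counts/placements), linkage disequilibrium and population
structure beyond what the GRM captures, overdispersed (beta-binomial)
methylation across biological replicates, non-uniform genomic
composition, and indels. Results on real libraries will be noisier than
the recovery benchmarks suggest, particularly for ASE (mapping bias)
and for DMRs with replicate-level dispersion.

# Problem sizes and reproducibility

The recovery and calibration studies run at deliberately modest sizes
chosen to exercise the stated conditions: a 1-Mb chromosome with 20
planted 3-kb DMRs at coverage 30 for DMR recovery; 10^4 loci at depth
100 for allele-fraction recovery; `n = 300`–`500` with 200–500 SNPs for
association calibration; 10^4 null instances for type-I error checks.
`run_pipeline()` writes a manifest with MD5 checksums of every output;
identical config + seed reproduces identical checksums.

`scripts/acceptance.R --seed <int> --out <path>` re-runs the summary
arithmetic and the recovery studies from scratch and writes the
resulting quantities as JSON.
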