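---
title: "Methods: sex-chromosome dosage analysis of oocyte transcriptomes"
author: "oodosage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-chromosome dosage analysis of oocyte transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oodosage)
```

# The scientific problem

Somatic cells balance X-linked gene expression by two mechanisms: X
upregulation toward autosomal levels in cells with one X, and X
inactivation in cells with two. Oocytes reactivate the silent X before
meiosis, so during follicular growth neither mechanism is guaranteed to
operate. Comparing oocytes with one X (XO), one X plus a Y (XY
sex-reversed females), and two X chromosomes (XX) turns X dosage into an
experimental variable: a gene transcribed independently from each X copy
should show XO and XY levels at half the XX level, while a
dosage-compensated gene should show equal levels in all three genotypes.
The Y-bearing genotype additionally reveals which Y-linked and
pseudoautosomal (PAR) genes are transcribed outside the male germline.

`oodosage` implements the complete computational path for this design —
5′ UMI counting, spike-in normalization, three-way differential
expression, and the dosage statistics proper — plus a synthetic-data
generator that encodes the design's ground truth, so each stage is
testable without any sequencing data.

# The synthetic-data generator

The generator is a first-class module, not a test fixture. It emulates:

* **Design**: three genotypes in biological triplicate (9 samples);
  a gene universe over autosomes 1–19, the X, the Y (with PAR genes
  distal on Yp), and 92 ERCC-like spike-in features.
* **Truth classes**: X-linked genes are split between
  `dosage_dependent` (XO = XY = ρ·XX with ρ = 0.5, i.e. per-allele
  transcription) and `compensated` (equal across genotypes); Y-linked
  genes are `y_high`, `y_medium`, or `y_silent` (always zero in XX and
  XO); PAR genes are elevated in XY; autosomes are neutral. These
  equalities hold *exactly* in the truth table and are asserted
  per-gene by the tests.
* **Expression scale**: baseline means are lognormal
  (`meanlog = log(3)`, `sdlog = 2.3` by default), spanning more than
  four orders of magnitude so that six expression bins are
  non-degenerate.
* **Noise**: counts are Poisson(mean × lib × exp(ε)) with
  ε ~ N(0, sdlog²), sdlog = 0.2 by default, and lognormal per-sample
  library factors (sdlog 0.15, geometric mean 1). Spike-ins carry *no*
  biological noise — they are technical material added to the lysis
  buffer — which is what makes them usable for separating technical
  from biological variance in recovery tests. A Poisson-lognormal
  rather than negative-binomial parameterization keeps that separation
  explicit.
* **Spike fraction**: total spike molecules target 4.5% of molecules,
  the middle of the 3–6% design band for this protocol.
* **Reads**: each molecule receives a UMI uniform over the 4¹² 12-mers
  and one tagged 5′ read (anchor + UMI + `ACG` + G-stretch + cDNA).
  Each gene has one fixed cDNA sequence, as reads aligned to one gene
  would. Untagged internal reads are added at a configurable fraction
  (default 0.5 — the observed fraction is not documented for this
  protocol, so this is an explicit guess exposed in the config), and
  substitution errors are applied per base (default 0.001). Reads are
  single-end: only the tagged 5′ read carries quantification signal,
  so the mate adds nothing at the level this model operates.

What the generator does **not** emulate: genome sequence and alignment
ambiguity (gene assignment is an explicit input, produced by the
generator or by any external aligner), UMI errors correlated with PCR
cycles, overdispersion beyond lognormal-Poisson, intron structure, or
oocyte growth stages. Passing recovery tests therefore demonstrate the
correctness of the pipeline's statistics, not robustness to alignment
artifacts.

UMI collisions are allowed (two molecules of one gene may draw the same
12-mer) and not corrected. The generator reports both the molecule
matrix and the realized distinct-UMI matrix; deduplicated counting is
exact against the latter, while the former differs by the handful of
collisions expected at desk scale.

# Tag detection and UMI counting

A read matches the tag when the anchor occurs within a start offset of
at most 5 with at most 1 mismatch, followed by exactly 12 UMI bases
(no `N`), the literal `ACG`, and at least 2 `G`s. The exact regular
expression used upstream of the original data is not recoverable, so
these tolerances are explicit `tag_pattern()` parameters. Two semantics
were fixed deliberately:

* the smallest *fully valid* placement wins — an anchor hit whose
  downstream layout fails falls through to later offsets, so the
  matcher agrees with a brute-force enumerator of all placements
  (property-tested on randomized reads);
* the G-stretch is consumed greedily, so the reported cDNA offset never
  begins on template-switch Gs;
* an `N` inside the UMI is a no-match rather than a wildcard, avoiding
  dedup ambiguity.

Counting is per distinct (gene, sample, UMI) triple; the same UMI under
two genes counts once for each. An optional directional Hamming-1
collapse (absorb a UMI into a strictly more frequent neighbour at
distance 1) is provided but off by default — the underlying protocol
analysis did not describe UMI error correction, and with 12-nt UMIs at
oocyte-scale counts the exact-identity rule is the conservative choice.

# Normalization and QC

Size factors are median ratios of observed spike counts to expected
molecules (`attomoles × 10⁻¹⁸ × N_A`), rescaled to geometric mean 1; at
least 8 detected spikes per sample are required. The median is robust to
individual spike dropout and uses the only stated anchor (spike-ins)
without inventing regression weights; whether the original analysis
normalized to per-spike expectations or totals is not documented, and
the median-ratio form recovers simulated capture ratios within 5%.

The log transform is `log2(x + 1)`. The variance-stabilizing transform
named in the upstream analysis is not publicly specified, so a standard
pseudocount log is used and the pseudocount is configurable.

QC reproduces the two standard views: PCA on centered log expression
(component signs fixed by the largest-magnitude loading, so scores are
deterministic), and a Spearman-correlation distance matrix of the top
500 genes. "Highly and variably expressed" is operationalized as: among
genes with mean log expression at or above the matrix-wide median, take
the `n` with largest variance, ties broken by feature id.

# Differential expression

Each gene is fit by OLS against intercept + genotype indicators (+
optional surrogate covariates), and the three pairwise contrasts are
read off the coefficients. Variances are moderated empirically:
residual variances are modelled as s₀²·F(d, d₀) draws, (d₀, s₀²) are
estimated by method of moments on log s² (the trigamma equation is
inverted by bisection to relative tolerance 1e-10, with the d₀ = ∞
pooled branch when the moment equation has no positive solution), and
the moderated t uses d₀ + d degrees of freedom. The limiting cases are
part of the contract: d₀ = 0 reproduces the ordinary per-gene t exactly,
d₀ = ∞ the fully pooled test; the general case agrees with the
established empirical-Bayes implementation to numerical precision
(cross-checked in the tests).

Surrogate covariates are the top left singular vectors of the residual
matrix after regressing out the primary design — a deliberate
simplification of iterative surrogate-variable estimation, sufficient
for the stated use ("covariates in the linear model") and directly
testable: a planted batch affecting 30% of genes is recovered with
|correlation| > 0.9, and including it restores type-I calibration that
is violated without it. The number of surrogates is chosen by
permutation parallel analysis comparing variance *proportions* (raw
singular values are biased because re-residualized permutations lose
rank and total variance).

Directional DEG lists use p < alpha (default 0.05) with an optional
|log₂FC| threshold (0 for the dosage Venn, 1 for the stringent
Y-focused lists). The four-set Venn partition is computed over X-linked
and autosomal universes separately, and the named categories are pure
set algebra on the 16 cells:

* red = (XX>XO) ∩ (XX>XY) \\ ((XY>XO) ∪ (XY<XO)) — X-dosage dependent;
* purple_solid = (XX>XO) ∩ (XY>XO) \\ (XX>XY);
* purple_broken = (XX>XY) ∩ (XY>XO);
* brown = (XX>XY) ∩ (XY<XO).

# Dosage statistics

**Ratio fit.** Per gene, the XO/XY:XX ratio is the geometric mean of
pseudocount-stabilized normalized expression across numerator
replicates over the same for XX (pseudocount 0.5 normalized units —
Y-linked and low genes have true zeros and the upstream handling is
undocumented). The pooled fit concatenates the XO- and XY-ratio log
vectors. The fit reports exp(mean log r) (geometric mean), the
multiplicative SD interval, and a t-based 95% CI.

**Bins and bootstrap.** Genes are sorted by mean normalized expression
(ties by feature id) and split into 6 contiguous bins whose sizes
differ by at most one (extras to the highest bins). The X:A statistic
per bin and genotype resamples 100 X-linked and 100 autosomal genes
with replacement — independently, which is what the sampling
description supports; paired draws were rejected — and takes the ratio
of median per-genotype mean expression, 5,000 times. Y-linked and PAR-Y
genes and spikes are excluded from the universe; PAR-X genes count as
X-linked. "Mean transcript level" is the arithmetic replicate mean for
bootstrap statistics but the geometric mean for ratio fits and homolog
summaries, following the distinct wording of the two procedures. The
bin-6 genotype bootstrap uses the same scheme with a paired statistic:
median XO (or XY) mean of the drawn genes over the median XX mean of
the *same* genes, which is exactly scale-equivariant (a noiseless
ρ = 0.5 simulation returns 0.5 identically).

Whether bins should be defined on pooled or per-genotype expression is
ambiguous; pooled was chosen (one binning shared by all genotypes, so
cross-genotype comparisons are within fixed gene sets).

**Y-gene classes.** log₂FC = log₂((mean_XY + 0.5)/(mean_XX + 0.5)) on
genotype means; high iff ≥ 3, medium iff strictly between 1 and 3, none
iff ≤ 1 (boundary semantics are property-tested at ±1e-12). BH-adjusted
p-values from the XXvsXY contrast are attached over the Y-gene subset.

**Homolog sums.** Member summaries are geometric means of
pseudocount-shifted replicate values with the population (1/n) SD of
logs — so replicates (2, 8) give geometric mean 4 with interval
(2, 8) — and the X+Y "sum" adds member geometric means per genotype, Y
members contributing zero in XX and XO. This is what makes XX (two X
alleles) comparable to XY (one X + one Y homolog).

# qRT-PCR module

Relative levels are efficiency^(−ΔCq) with ΔCq against a stable
reference gene; the efficiency is fixed at 2 (perfect doubling) because
no standard curves are available, and is configurable. Group
comparisons use Welch t, one-way ANOVA with Tukey HSD (studentized
range), or Kruskal-style rank sums with Dunn's pairwise z tests
(tie-corrected normal approximation). Dunn's multiplicity adjustment is
Bonferroni over the tested pairs — the upstream description names the
test but not the adjustment, and Bonferroni is the conservative
convention for it.

# Numerical and reproducibility choices

* Every stochastic function takes an explicit seed and restores the
  caller's RNG state; the pipeline derives per-stage seeds from one
  master seed (with optional per-stage overrides), so changing a
  downstream seed leaves upstream artifacts byte-identical, and reruns
  with one config hash to identical files.
* TSV artifacts format numerics at fixed significant digits; JSON is
  written with stable key order — determinism is asserted by md5 in the
  tests.
* Degenerate inputs are contracts, not crashes: constant columns in the
  Spearman distance warn and yield distance 1; all-identical variances
  take the pooled d₀ = ∞ branch; zero-variance genes with zero contrast
  get t = 0; p-values are floored at 1e-300 before BH.
* Problem sizes in the test suite are chosen for tight Monte-Carlo
  error at interactive runtimes: the full-scale end-to-end run uses
  ~5,000 genes + 92 spikes across 9 samples (≈3.6 M simulated reads)
  with 5,000 bootstrap repetitions; calibration checks use
  4,000–10,000 genes; recovery checks of the red (X-dosage-dependent)
  category plant 30% dosage-dependent X genes at high expression
  (baseline meanlog log(1000)), where per-gene power — not the
  partitioning logic — is no longer the limiting factor. At the
  low-expression tail of the default generator, Poisson noise caps
  red-category recovery below what the high-expression setting
  achieves; this mirrors real data, where dosage calls concentrate in
  well-detected genes.

# Known limitations

* Gene assignment of reads is an input; no aligner is bundled, so
  multi-mapping and positional biases are out of scope.
* The spike design table produced by the generator is synthetic; users
  with real data must supply their spike sheet (TSV with `spike_id` and
  `attomoles` or `expected_molecules`).
* The moderated model assumes a shared design across genes and no
  precision weights; duplicate-correlation and voom-style weighting are
  deliberately not implemented.
* The bootstrap treats genes as exchangeable within a bin; gene-length
  or GC effects are not modelled (UMI counts are length-free by
  construction).
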