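---
title: "Models and methods in discomod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in discomod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discomod)
```

`discomod` analyses small cohorts of brother pairs who share a causal
*ABCD1* mutation but are discordant for cerebral adrenoleukodystrophy
(CALD). This vignette documents the statistical models, the defaults and
the design decisions, and states plainly what the synthetic-data
generator does and does not emulate.

## The cohort design

The unit of analysis is the family: one CALD and one non-CALD brother,
close in age (the generator enforces an age difference of at most two
years, matching the cohorts this design targets). Unrelated adult male
controls participate only in the lipid ALD-vs-control comparison —
controls carry no family identifier and the cohort validator rejects any
sheet that blurs this. Everything downstream conditions on the pairing:
discordance is defined within a family, and the linear models absorb
between-family differences in a family cofactor.

## Genotype discordance

For a variant with both brothers called, the genotypic mode comes from
the carrier (heterozygous carrier: dominant; homozygous carrier:
recessive) and the direction from the carrier's phenotype (CALD:
damaging; non-CALD: protective). Two choices make the four categories a
partition of the discordant genotype pairs:

* dominant categories are strict — `0/1` against `0/0`;
* the homozygous carrier always defines the call, so `(1/1, 0/0)` and
  `(1/1, 0/1)` are both recessive damaging, never dominant.

Under Hardy–Weinberg background variation this asymmetry reproduces the
roughly two-to-one excess of dominant over recessive discordance that
such cohorts show, because a heterozygote–homozygote-reference pair is
far more common than a homozygote-alternate carrier.

Missing genotypes disqualify the variant *for that family only*. The
alternative — counting a no-call as discordant or concordant — fabricates
evidence in exactly the situations (low coverage, segmental events)
where genotypes are least reliable.

Cross-family intersection uses the exact disjoint partition: each
variant is assigned to the precise subset of families in which it is
discordant, within one category. We require the *same* category across
families for a variant to intersect; a variant dominant-damaging in one
family and recessive-damaging in another reflects two different genetic
models and is not treated as replication. Depth-k marginals are sums of
partition cells with |subset| = k, so the partition always sums to the
union of the per-family sets — a property the test suite re-checks on
random instances against a brute-force enumeration over all subsets.

Haploblocks are maximal runs of candidate variants with consecutive
gaps at most `haploblock_max_gap` (default 50 kb) and at least
`haploblock_min_size` (default 3) members — a deliberately simple
proximity rule, not an LD model, sufficient to flag co-inherited
candidate clusters such as a shared-heterozygote block spanning a gene.

Mitochondrial variants are compared through heteroplasmy states rather
than diploid genotypes: an allele fraction below 0.05 is absent, above
0.95 homoplasmic, and in between heteroplasmic. The 0.05–0.95 band is
our default (no published band exists for this analysis); it is the
conventional detection floor of mitochondrial variant callers and is
configurable (`het_low`, `het_high`). Brothers are discordant at a
variant when their states differ; gene-level aggregation takes the union
of genes hit per family before intersection.

## APOE and candidate alleles

APOE ε alleles are haplotypes of rs429358 and rs7412: (T,T) → ε2,
(T,C) → ε3, (C,C) → ε4, and the rare (C,T) → ε1. Unphased diploid calls
resolve uniquely when at most one site is heterozygous. The double
heterozygote is genuinely ambiguous (ε2/ε4 versus ε1/ε3); we report
ε2/ε4 — the ε1 haplotype is vanishingly rare in all populations — and
set an `ambiguous` flag rather than hide the uncertainty. Alleles are
read on the reported strand with T/C coding; no strand flipping is
attempted, so input tables must use the same convention.

## The univariate model

Every per-feature scan fits, by ordinary least squares,

$$y = \rho\beta + fam + \varepsilon,$$

with $\rho \in \{0,1\}$ the phenotype indicator and $fam$ fixed family
indicator variables; DNA methylation adds an age term (methylation
drifts with age, and the brothers differ in age by up to two years):

$$y = \rho\beta + fam + age + \varepsilon.$$

Residual degrees of freedom are $n - n_{fam} - 1$ (one fewer with age).
Family enters as fixed effects rather than random effects: for the
balanced one-pair-per-family design the phenotype estimate is identical
to the random-intercept fit, and the fixed-effect fit has a closed form
the tests can verify to machine precision — with no age term, $\hat\beta$
*is* the mean within-pair difference and the t statistic *is* the paired
t-test. Studies of this design have used moderated or count-based
likelihood machinery (limma, edgeR) for the array and count platforms;
this package deliberately fits the stated linear model itself on all
platforms, so its p-values are exact t-tests on the transformed scale
and will differ numerically from moderated analyses.

Platform transforms before fitting:

* **rna** — log2(CPM + 0.5), library sizes from total counts of the
  retained samples (recomputed inside every leave-out subset so no
  left-out sample leaks into normalization); all-zero features dropped;
* **dnam** — M-values, $\log_2(\beta/(1-\beta))$, the scale on which
  methylation differences are approximately homoscedastic; effect sizes
  are additionally reported as delta beta on the original proportion
  scale, where thresholds are interpretable;
* **lipid / protein** — log2 of the (positive, linear) abundances.

Degenerate fits (zero residual variance, e.g. noise-free constructions)
return the estimate with `NA` standard error and p-value plus a flag,
rather than a spurious zero p-value. If age has no within-family
variation it is collinear with the family indicators and is dropped with
a warning.

Multiple testing uses Bonferroni by default (matching the conservative
convention for these scans) with Benjamini–Hochberg available; both
delegate to `stats::p.adjust`, and the test suite checks them against
independently coded step-up/closed-form oracles.

## CpG filtering and DMR calling

CpG-level hits require a nominal p below `cpg_p` (default 0.0005) and an
absolute group-mean delta beta above `delta_beta` (default 0.05, i.e.
5% methylation change). Region calling is our own concretization — no
published algorithm or parameters exist for the analysis this package
implements — and is declared rather than inferred: candidate regions are
maximal runs of nominally significant CpGs with inter-CpG gaps at most
`dmr_max_gap` (default 1000 bp), a shared direction of change (runs split
at sign changes), and at least `dmr_min_cpgs` (default 3) members. The
region p combines member z-scores by Stouffer's method
($z_r = \sum_i z_i / \sqrt{k}$, so k equal-p members give
$\sqrt{k}\,z$), regions are FDR-adjusted across candidates
(Benjamini–Hochberg), and reported DMRs pass `dmr_fdr` (default 0.05)
and an absolute mean delta beta above `dmr_delta_beta` (default 0.10).
Member p-values within a run are correlated only through shared samples,
not through methylation autocorrelation, which the generator does not
model (below); on real arrays the Stouffer combination is therefore
mildly anti-conservative and the FDR threshold should be read as a
ranking device, as it is in all DMR callers of this family.

## Variance partitioning and sensitivity

Per-feature variance decomposes by sequential (type I) sums of squares
with entry order family → age → phenotype → phenotype:age (age terms
only for methylation). Entering family first is conservative for the
phenotype fraction: any variance explainable by either goes to family.
Fractions are term SS over total SS, sum to one by construction, and are
undefined for constant features (flagged, not zeroed). A mixed-model
variance decomposition would shrink the family fraction toward zero for
small effects; the sequential decomposition was chosen because it is
deterministic, closed-form and exactly testable against a projection
oracle.

Leave-families-out sensitivity re-runs the scan on every subset
obtained by removing up to `max_leave_out` families (default 2): with
six families that is 1 + 6 + 15 = 22 labelled runs (`all_families`,
`wo_<fam>`, `wo_<fam>_<fam>`). The hit threshold is the nominal
p < 0.05 — the convention used when intersecting nominal hits across
platforms; no separate published threshold exists for the subset runs.
Per-subset hit sets are summarized with the same exact upset partition
as the genotype engine. Methylation is excluded from the sensitivity
analysis by convention (its age covariate makes subset comparisons
non-exchangeable); the functions do not enforce this, the pipeline
simply does not call them with dnam.

## Integration

Feature hits collapse to genes by keeping the minimum-p feature per
(gene, platform) — the rule is ours; ties break on feature id for
determinism. The four intersections (DNAm–RNA, DNAm–protein,
RNA–protein, all three) are annotated with direction arrows in the fixed
platform order dnam, rna, protein, e.g. `GENE(↑ – ↓)`. Lipids lack a
defensible gene mapping and never enter gene intersections, but do enter
the per-family log2-fold-change matrices (top 10 plus all p < 0.05 per
platform), where RNA uses CPM + 0.5 and lipid/protein use raw positive
abundances with no pseudocount. Family scores come from a
feature-centered SVD; clustering is agglomerative with average linkage
on the first three components, defaulting to two clusters because the
substantive question is a two-subgroup hypothesis; the count is a
parameter, and families with identical profiles always share a cluster.

## The synthetic-data generator

The generator produces the study conditions the analysis assumes: six
families (configurable) with sibling ages 6–38 years at most two years
apart, eight unrelated adult controls for lipids, genotype tables with
planted discordant alleles per category at chosen intersection depth on
a Hardy–Weinberg background (each brother drawn independently, so
incidental discordance arises naturally), and omics matrices following
the model above with the family effect drawn once per feature per family
and shared by both brothers — which is what makes the variance partition
testable against known ground truth.

All latent effects are on a log2 scale (log2 abundance; log2 count mean;
log2 methylated/unmethylated odds, i.e. the M-value scale), so a planted
β is in the same units the scan estimates. Emission per platform: lipid
and protein as `2^latent` linear abundances; RNA as negative-binomial
counts with mean `2^latent` and dispersion `rna_dispersion` (an
overdispersed integer platform is required for the CPM/log pipeline to
be exercised meaningfully); methylation as `plogis(latent·log 2)`
clamped to the open unit interval. Defaults — family SD 0.5, residual
SD 0.5 (log2 units), RNA dispersion 0.1 around a baseline mean of 500
counts, methylation baseline around 30% with an age drift of 0.02
log2-odds per year — are ordinary magnitudes for blood-derived omics;
no published effect sizes exist for true modifiers, so planted βs in
tests are chosen for statistical power, not biological realism. Because
the published ALD-vs-control contrast needs an effect the family model
does not contain, `simulate_omics()` has a `control_shift` parameter
offsetting affected samples from controls at signal features.

What the generator does **not** emulate — and therefore what passing
tests do not demonstrate about real data: linkage disequilibrium
(planted haploblocks are constructed, not recombined), methylation
autocorrelation beyond the clustered-CpG option (k CpGs sharing one
signal within a fixed gap), count library-size heterogeneity between
samples, batch structure, and cell-composition effects. Tests
demonstrate that the machinery is correct under its own model, not that
the model captures every feature of EPIC arrays or LC–MS.

A single integer seed drives each generator call through R's RNG, so
fixtures are bit-reproducible.

## Numerical choices

* Scans solve the shared design once (QR / normal equations on a
  well-conditioned 7–8 column matrix) and apply it to all features as a
  matrix product; the single-feature path uses the same engine, so the
  two agree bitwise.
* Degeneracy is declared when the residual variance falls below
  `1e-16` times the feature's mean square — effectively exact-fit
  detection, scale-invariant for the magnitudes these platforms produce.
* Output tables sort by ascending p then feature id; all set outputs
  sort lexicographically — ties never reorder across runs.
* Coordinates are 1-based inclusive (VCF convention) throughout; sites
  are points, so no strand handling exists anywhere.
* Multiallelic sites split into biallelic records keyed
  `chrom:pos:ref:alt`; symbolic SV/MEI records keep their caller id.

## Problem sizes

The shipped tests run the calibration and recovery checks at 200
replicates of 2,000 features (null calibration, three transforms) and
200 replicates of 40 features (effect and age-slope recovery), sizes at
which the Monte-Carlo standard error of a type-I rate is a few times
10⁻⁴ — small enough to detect a miscalibrated test, large enough to run
routinely. The acceptance script uses 100 replicates of 1,000 features
for the same quantities.

## Limitations

* Fixed-effect family adjustment matches the balanced paired design; it
  is not a general pedigree model and the package should not be pointed
  at cohorts with more than two siblings per family without rethinking
  the design matrix (the validator will refuse them).
* The DMR caller's thresholds are declared defaults, not estimates; on
  real arrays they should be tuned against a permutation baseline.
* P-values on the RNA platform are exact only conditionally on the
  log-CPM transform being adequate; very low counts (mean below ~10)
  leave discreteness the transform cannot remove.
* The intersection logic treats hit sets as exchangeable evidence;
  it does not model the correlation between platforms measuring the
  same biology, so intersection counts are descriptive, not inferential.
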