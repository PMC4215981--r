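---
title: "Methods: pedigree-based association mapping and QTL validation"
author: "pedQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree-based association mapping and QTL validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pedQTL` dissects quantitative trait loci in small, highly related inbred
panels — the situation of a breeding programme that wants to understand,
after the fact, which loci make its best variety good.  This vignette is
the package's own account of the models and the choices behind them.
Everything here is computed by the package's functions; numerical claims
are the ones its test suite and `scripts/acceptance.R` verify.

## Phenotype model and heritability

Multi-environment trials are modelled as a two-way crossed design with
random genotype and environment effects.  Replicates within an
environment are averaged first, so the analysis table has one value per
(genotype, environment) cell; with `g` genotypes and `e` environments the
residual stratum has `(g-1)(e-1)` degrees of freedom and doubles as the
genotype-by-environment term, which this design cannot separate from
plot error.  Variance components come from the expected mean squares:

* `var_resid = MS_error`
* `var_g = (MS_genotype - MS_error) / e`
* `var_e = (MS_environment - MS_error) / g`

with negative estimates truncated to zero and flagged.  Broad-sense
heritability is the genotypic share of the **total** phenotypic variance,

H² = σ²G / (σ²G + σ²E + σ²ε).

The denominator deliberately includes the environment component: with the
worked-example mean squares (MS_G = 61.76 at F = 19.65, MS_E = 475.57, 65
genotypes, 9 environments) this form — and only this form — gives the
published 38.5% (6.513 / 16.924).  A definition without σ²E would give
67%.

Genotypic values for association mapping are the plain means over
environments; environment correlations (computed on pairwise-complete
accessions) justify that averaging when they are uniformly positive.

Trait-to-trait correlations are reported overall and within the soft and
hard kernel strata, because the kernel-texture dichotomy shifts several
milling traits jointly and can manufacture correlation between traits
that are unrelated within either class (a Simpson's-paradox structure the
test suite constructs explicitly).

## Genotype curation

All genotypes are biallelic 0/1 calls on inbred lines; heterozygotes are
outside the data model.  Curation follows the order: MAF filter (default
0.1, computed over non-missing calls), redundancy removal (markers with
byte-identical call vectors, including the missingness pattern, collapse
to the first in map order), then kNN imputation — Manhattan distance over
mutually observed markers (normalised as mean absolute difference so
accessions with different missingness are comparable), `k = 3`
unweighted neighbour average rounded to the nearer code, accessions under
80% data dropped.  PCA is correlation-based (markers standardised), with
component signs fixed by making each component's largest loading
positive.  The UPGMA dendrogram uses average linkage on identity-by-state
distances with a deterministic tie-break (lexicographically smallest
member id), so trees are reproducible across platforms.

## Kinship and the mixed-model scan

Kinship is allele-sharing similarity — the proportion of matching calls
over mutually observed markers — linearly rescaled so the minimum
off-diagonal is 0 and the diagonal 1.  The exact formula used by the
original TASSEL analysis is unpublished; allele sharing with
min-rescaling is adopted and documented as this package's definition.

The scan fits, per marker,

y = μ + β_k·kernel + β_m·x + u + ε,  u ~ N(0, σ²g·K),  ε ~ N(0, σ²e·I)

on the genotypic values, with the 0/1 hard-kernel indicator as a fixed
covariate.  The variance ratio λ = σ²g/σ²e is estimated by REML through
one spectral decomposition of K: after rotating y and X by K's
eigenvectors the restricted likelihood is a cheap 1-D function of λ,
maximised by a coarse grid plus local optimisation (boundaries checked).
By default λ is estimated once under the null model and reused for every
marker — the "population parameters previously determined" shortcut; an
exact per-marker refit sits behind `exact = TRUE` and is affordable at
n = 65.  Marker significance is the F-test on β_m; the reported effect is
β_m oriented so that a positive value means the focal line's allele
raises the trait (x ∈ {0, 1} for inbreds, so the effect is the full
homozygote substitution effect); marker R² is the marker's share of the
weighted total sum of squares.  Markers confounded with the covariates
(including monomorphic ones) are skipped with a reason.

False-discovery control uses Storey q-values: π₀ estimated by the
smoother method (π̂₀(λ) over λ = 0, 0.05, …, 0.90, cubic smoothing spline
with 3 df evaluated at 0.90, falling back to 1 outside (0, 1] or when
fewer than 8 p-values are available), and
q_i = min over t ≥ p_i of π₀·m·t / #{p ≤ t}, clipped to [0, 1] and
monotone in p.  The default significance threshold is q < 0.5 —
permissive by genome-wide standards, matching the screening character of
the workflow; it is a configurable parameter, not a recommendation.

Calibration: on null panels (no planted QTL, polygenic trait, 65 lines,
1,000 markers over ten linkage groups) the scan's p-values are uniform
(Kolmogorov–Smirnov statistic < 0.05 in ≥ 90% of 50 replicates), while an
identity-kinship scan of the same data is visibly inflated.  The KS check
spreads the markers over ten linkage groups because the statistic assumes
independent p-values; with dense within-group linkage the same calibrated
scan shows larger KS values through correlation alone.

## QTL classification, LD blocks, origin tracing

Significant markers are grouped within (map source, linkage group) by
transitive closure of a gap relation: consecutive markers ≤ `gap_cm`
apart merge.  The default of 15 cM is chosen so that a 61.0–71.7 cM
cluster stays one QTL while a marker ~19 cM away starts another, matching
the worked examples that motivated the grouping; SNP-derived and
DArT-derived maps are grouped separately, and overlaps between maps are
reported rather than merged.  Labels are `<group>` or `<group>.<index>`
in position order.

The LD block around a QTL is the maximal run of consecutive genotyped map
markers containing a QTL member in which every adjacent pair has
r² ≥ 0.7 (squared Pearson correlation of allele codes — identical to
haplotype r² for inbred biallelic data); a block is "present" with ≥ 3
markers.  The source study never states its block criterion; this
adjacent-pair rule is the package's definition and both thresholds are
exposed as configuration.

Within-block similarity to the focal line is the fraction of identical
calls over mutually observed block markers.  An accession is a *carrier*
at similarity ≥ 0.9 (again a package default; the figure the study used
is unstated).  Origin classification walks carrier-only paths up the
pedigree from the focal line: only the mother's side carrying gives
"maternal", only the father's "paternal", both "both/undetermined".
Source ancestors are carriers with no carrying parent on those paths; a
non-founder carrier with no carrying parent flags a discrepancy with the
pedigree record, which is exactly how introgressions absent from the
written pedigree announce themselves.

## Marker conversion and in-silico PCR

Converting an array SNP into a PCR assay for hexaploid wheat needs two
layers of specificity.  Genome specificity: both genome-specific primers
(GSPs) anchor their 3'-terminal base on a site where the target subgenome
differs from both homoeologs, with the amplicon in 150–600 bp and the SNP
at one third (± 0.1) of the primer interval measured from the nearer
primer.  Allele specificity: each allele-specific primer (ASP) ends
exactly on the SNP and carries an engineered mismatch at the third base
from the 3' end — a fixed transversion map (A↔C, G↔T) chosen for
determinism, standing in for the published-elsewhere mismatch-selection
heuristics.  Each genotyping reaction contains both GSPs and one ASP, so
a matching allele shows two bands (GSP product plus the shorter ASP
product on the one-third side) and a non-matching allele one band.

In-silico PCR is an engineering contract, not thermodynamics: a primer
binds iff its 3'-terminal base matches, with ≤ 1 mismatch in its
3'-terminal 5 bases and ≤ 3 overall, ungapped; amplicons are enumerated
for every convergent bound pair within 2 kb.  Under this rule the
3'-anchored GSP design makes off-subgenome templates yield zero bands.
Melting temperatures use the SantaLucia (1998) unified nearest-neighbour
parameters at 0.25 µM primer with the salt term at the monovalent
equivalent of a standard PCR buffer (50 mM KCl + 1.5 mM MgCl₂ ≈ 150 mM);
the default annealing window is 55–62 °C.  Homoeolog retrieval from a
contig database uses local alignment (match +1, mismatch −2, affine gaps
4/1) with a minimum score of half the probe length — calibrated so
97%-identical homoeologs pass and unrelated sequences fail — in place of
an external BLASTN dependency; the contig matching the probe perfectly
designates the target subgenome.

On synthetic homoeolog triplets (1 kb, 3% pairwise divergence) the
design-plus-validation chain passes for ≥ 90% of cases (the acceptance
suite measures ~98/100); failures are almost exclusively triplets whose
discriminating-site placement admits no primer pair with both melting
temperatures in the annealing window.

## Doubled-haploid validation

Allele-mean tests are two-sided pooled-variance t-tests (the original
analysis says only that a t-test was used; pooled is this package's
documented choice), reporting the focal parent's allele class first and a
missing p-value for monomorphic markers rather than an error.  The
prediction models are ordinary least squares on 0/1 marker codes: the
combined fit (DH_total) includes population intercepts to absorb
between-cross mean differences — the package's reading of "based on the
three combined populations", computable without intercepts behind the
same function — while per-population fits (DH_each) refit everything
within each cross.  Markers aliased within a fit (tightly linked loci
segregating identically in a biparental cross) either raise an error
naming the collinear markers or, on request, drop to one representative.
On simulations where marker effects genuinely differ between crosses, the
pooled correlation of DH_each exceeds DH_total in ≥ 80% of replicates.

## The synthetic study and what it does (not) show

`simulateBreedingStudy()` builds the whole study the analysis assumes: a
focal line bred from paired founder intermediates, a 65-line panel filled
out with crosses among the lineage (strong kinship), 2,000 markers on
five 150 cM linkage groups, nine environments with two replicates,
variance components (σ²G, σ²E, σ²ε) = (6.5, 7.3, 3.1) trait-units² —
chosen because they reproduce the worked example's 38.5% heritability and
printed mean squares — twelve planted additive QTLs with effects drawn
once from 1.5–2.7 trait units, a kernel locus with a 4-unit fixed effect
on a 5D marker (soft:hard about 48:17), 2% missing calls, and three DH
populations of 151 lines from crosses chosen to segregate for the planted
QTLs.  Meiosis follows the Haldane (no-interference) model with one
meiosis per derived line; every simulated allele traces to a founder
allele, which is what makes the origin-tracing oracle possible.

Two deliberate subtleties:

* The polygenic line value is built from the genotypes (many small
  seeded marker effects rescaled to σ²G), not drawn independently —
  relatives therefore resemble each other, which is precisely what makes
  the naive no-kinship scan inflate on null data and the K-corrected scan
  calibrate.  `var_residual` is defined at the environment-mean level
  (plot noise is scaled up by the replicate count), so the ANOVA's error
  stratum estimates it directly.
* Founders are mosaics of three ancestral haplotypes (~30 cM segments) by
  default, giving the panel the local LD of a real breeding pool so that
  LD blocks exist to detect; with mosaic founders marker allele
  frequencies hold in expectation only.  Passing `nAncestral = NULL`
  draws founder alleles independently per marker (exact per-marker
  frequencies, near-zero local LD) — the setting used for calibration
  checks.

With the planted QTLs and the kernel effect included, the study trait's
total heritability exceeds the 0.385 component ratio — the planted
marginal effects add genetic variance that the published effect estimates
(being overlapping, LD-shared and winner's-curse-inflated) do not imply
for the real trait.  Heritability-recovery checks therefore run on
components-only simulations, where the estimator recovers 0.385 within
Monte-Carlo error (±0.08 over 200 replicates).  More generally, the
generator emulates the *statistical structure* the methods assume — it
does not emulate genotyping error, segregation distortion, selection
during line development, genotype-by-environment interaction (confounded
with error in this design, hence excluded), or epistasis.  Green tests on
synthetic data show the machinery is correct under the stated model, not
that the model captures every feature of real panels.

## Numerical and degenerate-input conventions

Sequence offsets are 0-based half-open internally and 1-based inclusive
in reports.  All stochastic functions take explicit seeds and restore the
caller's RNG state; the pipeline derives stage seeds from one master
seed, making `runPipeline("all", …)` byte-reproducible.  Degenerate
inputs prefer typed errors (cyclic pedigrees, ragged files, unknown
genotype codes, accession pairs sharing no markers) or flagged missing
values (monomorphic t-tests, undefined F on constant tables, correlations
on < 3 shared accessions) over silent coercion.  Problem sizes in the
test and acceptance runs (65-line panels, 1,000–2,000 markers, 50–200
replicate properties, 100–200 primer triplets) are the package's chosen
desk-scale study conditions.

## Known limitations

The kinship formula, LD-block criterion, carrier threshold and ASP
mismatch rule are documented package definitions standing where the
original analysis left its choices unstated; reproducing that analysis's
exact marker counts on its own data is therefore implementation-sensitive
even with the journal's datasets in place.  Narrow-sense heritability,
Q-matrix structure covariates, multi-locus models, interval mapping and
thermodynamic primer screening are out of scope.
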