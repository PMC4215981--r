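# pedQTL

Pedigree-based association mapping and QTL validation for inbred breeding
panels.

## The problem

Milling traits such as flour yield (FlYd, the percentage of flour recovered
from a milled grain sample) are expensive to phenotype and strongly
environment-dependent, so selection happens late in a breeding programme.
When a panel of breeding lines related through a known pedigree has already
been phenotyped across environments and genotyped genome-wide, the panel
itself can be mined for the quantitative trait loci (QTLs) behind a focal
variety's superiority — provided the analysis accounts for the two things
that dominate such panels: strong familial relatedness and the soft/hard
kernel dichotomy controlled by the puroindoline loci.

`pedQTL` implements that workflow end to end for fully inbred material
(breeding lines and doubled haploids):

* **Phenotype analysis** — two-way random-effects ANOVA on genotype x
  environment means, method-of-moments variance components, broad-sense
  heritability H² = σ²G / (σ²G + σ²E + σ²ε), environment correlations, and
  kernel-type-stratified trait correlations.
* **Structure and association** — MAF/redundancy filtering, kNN imputation
  (Manhattan distance, unweighted neighbour average), correlation-based
  PCA, identity-by-state distances with a deterministic UPGMA dendrogram,
  an allele-sharing kinship matrix K, and a mixed-linear-model scan
  y = Xβ + u + ε with u ~ N(0, σ²g·K), the kernel type as a fixed
  covariate, EMMA-style spectral REML for the variance ratio, and Storey
  q-values for FDR control.
* **QTL classification and pedigree tracing** — map-gap grouping of
  marker-trait associations (MTAs) into QTLs, adjacent-pair r² LD-block
  detection, within-block similarity to the focal line, and tracing of
  each block's origin through the pedigree to its introducing ancestor.
* **Marker conversion** — turning an array SNP into a genome-specific +
  allele-specific PCR assay for hexaploid wheat (GSP pair anchored on
  subgenome-discriminating sites, ASPs ending on the SNP with an
  engineered transversion at the third base from the 3' end), verified by
  in-silico PCR under an explicit binding rule.
* **Doubled-haploid validation** — pooled-variance allele-mean t-tests and
  multi-marker least-squares prediction, comparing a combined-population
  model (DH_total) against per-population models (DH_each).
* **Synthetic data** — a generator for pedigrees, inbred genotypes
  (Haldane meiosis), multi-environment phenotypes with chosen variance
  components, DH populations and homoeologous contig triplets, so the
  entire pipeline is testable without external data.

## Worked example

```r
library(pedQTL)

# a complete synthetic study: 65-line pedigree panel, 2,000 markers,
# 9 environments, planted QTLs, kernel locus, 3 DH populations
st  <- simulateBreedingStudy(SimulationConfig(seed = 1))

# heritability from the variance decomposition
an  <- twoWayAnova(st$phenotypes, "FlYd")
vc  <- varianceComponents(an)
round(100 * broadSenseHeritability(vc), 1)
#> [1] 59.3

# genotypic values, kinship, kernel-corrected mixed-model scan
gi  <- knnImpute(filterMarkers(st$genotypes, 0.1, map = st$map), k = 3)
y   <- envCorrelations(st$phenotypes)$genotypic_values
mta <- mlmScan(gi, y, kinshipMatrix(gi), covariates = st$kernelType,
               focal = st$focal, map = st$map)
sum(mta$q_value < 0.5)
#> [1] 29

classifyMTAs(mta, gapCm = 15)[, c("qtl_id", "n_markers", "cm_start",
                                  "cm_end", "effect")]
#>   qtl_id n_markers cm_start cm_end effect
#> 1   1A.1        13    19.92  31.95 -1.083
#> 2   1A.2         4   104.89 107.89 -3.376
#> 3     2B         3    27.07  34.96 -2.809
#> 4   5D.1         4    27.82  33.08  2.724
#> 5   5D.2         1    91.35  91.35  2.452
#> 6   5D.3         4   119.55 124.81 -2.887
```

(The heritability of the full study trait exceeds the 38.5% component
ratio because the planted QTLs and the kernel locus add genetic variance
on top of the polygenic component; see the methods vignette.)

The same stages run as a file-based pipeline:

```r
runPipeline("all", pipelineConfig(outDir = "out", seed = 1))
```

or from a shell via the thin wrapper `inst/scripts/pedqtl.R`.

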