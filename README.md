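# DimorphScreen

Males and females differ systematically in metabolism and behavior — fat
storage, stress survival, feeding, sleep — and the gut's enteroendocrine
cells (EECs) are a major endocrine source shaping those differences. This
package implements the computational machinery for studying that
dimorphism in the *Drosophila* midgut: spatial mapping of EECs along the
gut axis with length-scaled regional statistics, reduction of multi-assay
phenotype data (survival, metabolites, sleep, feeding) to per-genotype
trait values, a screen-wide hit-calling and sex-specificity layer, and a
multivariate layer that places knockdown phenotypes in a common space and
measures how male-like or female-like they are. It is written for
researchers running EEC-targeted RNAi screens or gut-anatomy comparisons,
and for anyone who wants a tested, synthetic-ground-truth harness for this
class of analysis.

## The statistics at the core

**Regional enrichment.** Female guts are longer (ratio *r* ≈ 1.4), so each
of the ten equal-arc-length deciles is expected to hold more cells even at
identical density. With per-decile counts *N<sub>d</sub>*, the expected
female count is *E<sub>f</sub>[d] = r · mean(N<sup>male</sup><sub>d</sub>)*
and the reported ratio is
*R<sub>d</sub> = mean(N<sup>female</sup><sub>d</sub>) / E<sub>f</sub>[d]*,
with bootstrap 95% CIs and per-decile Welch t-tests under Holm–Šidák
adjustment. *R<sub>d</sub>* > 1 marks female overabundance beyond length
scaling.

**Hit calling.** Phenotypes become z-scores against the sex-matched
control, scaled by the SD across all knockdown means; a hit is |z| > 1.5
(strict), with no multiple-testing correction. Per-trait Venn triples
(male-only *M*, female-only *F*, shared *S*) yield the sex-specificity
fractions, e.g. the female shared fraction *S/(F+S)* and male-specific
fraction *M/(M+S)*.

**Multivariate layer.** Hierarchical clustering on 1 − Spearman rank
correlation with average linkage; centered-SVD PCA of pooled z-normalized
trait values; Euclidean distances in the PC1×PC2 plane from each knockdown
to the opposite-sex control, and between each genotype's male/female pair.

Everything upstream of these statistics — two-channel gut images with a
curved tube, DAMS activity series, FLIC event lists, interval-censored
survival counts, replicate-level screen tables — can be simulated with
planted ground truth, so the full chain is testable offline.

## Worked example

Simulate a cohort of 10 female and 10 male guts with a planted 2.5-fold
GFP⁺ enrichment in deciles 3–5 of females, quantify each image (axis
trace, nucleus and GFP segmentation, decile binning), and run the
enrichment analysis:

```r
library(DimorphScreen)

p <- gutSimParams(enrichmentDeciles = 3:5, enrichmentFold = 2.5,
                  seed = 7011)
coh <- simulateGutCohort(p, 10)
qf <- lapply(coh$female, function(s) quantifyGut(s$image))
qm <- lapply(coh$male,   function(s) quantifyGut(s$image))
enr <- enrichmentAnalysis(qf, qm, nBoot = 1000, seed = 1)
enr
#> EnrichmentResult: 10 female vs 10 male guts, length ratio 1.401
#> observed/expected by decile:
#>    d1    d2    d3    d4    d5    d6    d7    d8    d9   d10
#> 0.831 1.279 1.147 2.676 2.411 2.566 0.952 1.032 0.997 1.347

round(adjustedPValues(enr), 4)
#>  [1] 0.3739 0.2587 0.7872 0.0000 0.0000 0.0000 0.9609 0.9609 0.9819 0.3097
```

The estimated length ratio recovers the planted 1.4; the observed/expected
ratios sit near 2.5 exactly in the planted deciles (d4–d6 in 1-based
labels) and near 1 elsewhere, and only the planted deciles survive
Holm–Šidák adjustment.

Screen-side, the sex-specificity fractions follow exactly from integer hit
counts — for a trait with 89 male-only, 8 female-only and 38 shared hits:

```r
vennTriple(89, 8, 38)[c("femaleShared_pct", "maleSpecific_pct")]
#> $femaleShared_pct
#> [1] 83
#> $maleSpecific_pct
#> [1] 70
```

meaning 83% of knockdowns that affected females also affected males, while
70% of male hits were male-specific.

`runPipeline(defaultRunConfig())` chains the whole workflow — simulate,
quantify, assay reduction, hit calling, clustering and PCA distances —
into an output directory with tidy CSVs and a JSON run manifest.

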