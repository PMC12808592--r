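---
title: "Methods: quantifying sex dimorphism in the gut endocrine system"
author: "DimorphScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying sex dimorphism in the gut endocrine system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

DimorphScreen implements the computational core of a sex-dimorphism screen
of the *Drosophila* gut endocrine system: (i) spatial quantification of
enteroendocrine cells (EECs) along the midgut with length-scaled
regional-enrichment statistics; (ii) reducers that turn raw survival,
metabolite, sleep and feeding records into per-genotype trait values;
(iii) a screen-wide statistical layer (z-score hit calling, sex-specificity
Venn statistics, trait correlations); and (iv) a multivariate layer
(Spearman average-linkage clustering, centered-SVD PCA with
phenotypic-space distances to opposite-sex references). Because no public
imaging or screen data are deposited for this kind of experiment, the
package ships first-class synthetic-data generators with machine-readable
ground truth; every downstream stage is tested against planted truth.

# The anatomical model and its statistics

## Length-scaled expected counts

Female midguts are longer than male midguts (ratio $r \approx 1.4$) and so
contain more cells of every type even when the per-length density is
identical. The regional analysis therefore asks where females deviate from
the *length-only* expectation. Each gut is divided into ten equal
arc-length deciles ($d = 0..9$; half-open bins $[d/10,(d+1)/10)$, the last
bin closed). With $N_d$ the per-decile cell count, the expected female
count is

$$E_f[d] = r \cdot \overline{N^{male}_d}, \qquad
  r = \overline{L_{female}} / \overline{L_{male}},$$

and the reported statistic is the observed/expected ratio
$R_d = \overline{N^{female}_d} / E_f[d]$. $R_d > 1$ marks regional
overabundance in females. Uncertainty is a percentile bootstrap over guts
(default 2000 resamples; the resampling re-estimates $r$ as part of the
estimator). Per-decile significance is a Welch two-sample t-test of
observed female counts against length-scaled male counts, Holm–Šidák
step-down adjusted across the ten deciles
($\tilde p_{(i)} = 1-(1-p_{(i)})^{m-i+1}$, monotonized). Group
comparisons of scalar per-gut quantities (length, counts, densities) use
Welch's unequal-variance one-way ANOVA with Dunnett T3 all-pairs post hoc
tests; T3 p-values come from the studentized maximum modulus distribution,
evaluated by numerical integration over the chi scale density
(`pSMM()`), with Welch–Satterthwaite degrees of freedom per pair.

## Axis tracing

Gut length is the arc length of the *geodesic* path between the manually
marked anterior and posterior endpoints through the tissue foreground, not
the straight endpoint distance: guts remain curved after mounting, and the
chord would systematically understate female length and bias $r$ downward.
The mask is built by Gaussian blur, Otsu thresholding and a morphological
closing (default radius 9 px) that merges the nucleus-dense tissue into a
connected tube. The path is found by Dijkstra search on the 8-connected
pixel graph whose edge costs penalize distance from the medial axis
(via the mask's distance transform, penalty weight 4), so the path follows
the tube centre instead of cutting corners; its pixel chain is smoothed by
a running mean (window 15 px) before the polyline length is measured. A
straight-line mode (`traceAxis(..., mode = "endpoint")`) is retained as a
documented switch. On planted curved guts the traced length is within 2%
of the generator's true arc length.

## Segmentation

Nuclei are segmented by Gaussian blur (default $\sigma = 1$ px), Otsu
threshold, and a watershed on the masked blurred *intensity* with
tolerance 0.02 and a 5 px² minimum area. An intensity-peak watershed is
used deliberately: at tissue-like densities the thresholded nuclei merge
into a continuous band, and a distance-transform watershed then segments
the band's geometry (its ridge follows the tube) rather than individual
nuclei, which each remain a distinct intensity peak. Because watershed
regions also absorb surrounding dimly stained tissue, centroids are
computed from each object's bright core (pixels above the midpoint
between the object's peak and the global threshold) rather than from the
whole region — a whole-region weighted centroid is dragged off the nucleus
wherever a large tissue chunk attaches asymmetrically.

A nucleus is called GFP-positive when the mean GFP intensity in a 3 px
disk at its centroid exceeds a robust background threshold: the 10th
percentile of the GFP channel within the tissue mask plus $k = 5$ times
the MAD of the below-median pixels. Two details matter. Restricting the
statistics to the tissue mask keeps the threshold independent of how much
empty canvas an image happens to contain (longer, curvier guts have
proportionally more background; a whole-image threshold drifts with gut
geometry and biases GFP calls *between sexes*). Anchoring on the dim tail
rather than the median keeps the threshold valid whatever the GFP+
fraction, including tissues where nearly every nucleus is labelled.

# The screen model

## Hit calling

For each sex × assay, knockdown phenotypes are converted to z-scores
against the sex-matched control on the scale of the standard deviation
computed *across the means of all knockdowns* (control excluded by
default; a flag includes it). A hit is $|z| > \theta$ with $\theta = 1.5$,
strict inequality, and no multiple-testing correction — the fixed cutoff
is the screen's uniform definition of an extreme phenotype across
heterogeneous assays. Per-assay display scaling divides by the pooled
(male + female) maximum so the largest observed value is exactly 1.

Sex specificity is summarized per assay by crossing the two sexes' hit
sets on the shared gene universe into a Venn triple (male-only $M$,
female-only $F$, shared $S$) with derived fractions such as the female
shared fraction $S/(F+S)$ and the male-specific fraction $M/(M+S)$; the
printed percentages are rounded to integers. A sex with zero hits reports
a missing fraction, never 0.

## The ±1.5 SD rule's operating regime

The z-score denominator is an *empirical* SD across knockdown means. Two
consequences shape both the synthetic screen's defaults and the
calibration analyses:

* Planted true effects inflate that SD: a per-sex non-null fraction $f$
  with ±3 SD effects multiplies it by $\sqrt{1+9f}$, shrinking every z.
  The rule behaves as a Gaussian tail test only when the SD is
  noise-dominated, so the generator's default effect-class probabilities
  are sparse — null 0.94, shared 0.02, sex-specific 0.03, discordant 0.01
  — putting roughly 4–5% of gene × trait combinations per sex under a true
  effect, consistent with the sparse-effects assumption implicit in a
  fixed-SD screen cutoff.
* The control mean enters every z. With a control replicated like a
  knockdown, the null rate is $2(1-\Phi(1.5/\sqrt{2})) \approx 0.29$, not
  the tail value $2(1-\Phi(1.5)) \approx 0.134$. Calibration and recovery
  benchmarks therefore simulate the control genotype with 1000 replicates,
  making the control reference effectively exact, which is the regime the
  tail oracle describes.

Under those conditions, 200 pure-noise screens of 165 knockdowns hit at
the Gaussian-tail rate within binomial error, and 3-SD planted effects are
recovered (hit in at least one affected sex) with sensitivity above 0.9 at
a per-sex×trait false-hit rate consistent with the 13.4% tail.
Detecting a *discordant* gene requires both sexes past the cutoff
simultaneously, so its per-gene sensitivity is bounded by
$P(|z|>1.5)^2 \approx 0.87$ at 3-SD effects even with an exact control —
materially below the single-sex recall — and the corresponding test is
calibrated accordingly.

## Multivariate layer

Two profile-matrix modes feed clustering and PCA. `zdiff` rows are
z-scored differences from the sex-matched control (control rows exactly
zero): the question is how knockdowns deviate from their own sex's
baseline. `absolute` rows pool male and female genotype means and
z-normalize each trait across the pool: sex differences in trait magnitude
are preserved, male and female rows separate, and cross-sex distances are
meaningful. Clustering uses $1 - r_s$ (Spearman, pairwise-complete,
average ranks for ties) with average linkage, so any strictly increasing
transform of a profile leaves the dendrogram unchanged; constant profiles
are dropped with a warning. PCA is column-centered SVD with scores
$U\Sigma$; component signs are fixed by forcing each component's
largest-magnitude loading positive, making embeddings bit-reproducible.
Missing values are median-imputed per trait with a message (clustering
instead uses pairwise-complete correlations). Distances to the
opposite-sex control, and per-genotype male–female pair distances, are
Euclidean in the PC1 × PC2 plane (full-space distance behind a flag): a
female knockdown whose profile has drifted toward the male state ranks
near the male control, and a dimorphism-abolishing perturbation has the
smallest male–female pair distance.

# Assay reducers

* **Sleep** (DAMS beam-crossing series, 1-min bins): sleep is the total
  length of maximal runs of ≥ 5 consecutive zero-count minutes. Days run
  ZT0–ZT24 with the day phase `[lights-on, lights-on + 720)`; a run
  crossing the day/night boundary is split at the boundary minute (the
  convention is not dictated by the recording itself; splitting preserves
  total sleep additivity).
* **Survival** (interval-censored counts, 6–8 h checks, 3 vials × 20
  flies): death times are imputed at interval midpoints; the per-vial
  median is the replicate unit; genotypes are compared by one-way ANOVA
  with Tukey post hoc tests on vial medians. Interval-censored maximum
  likelihood would refine this but is out of scope; with 6–8 h checks the
  midpoint convention recovers exponential medians to within one check
  interval at n = 1000.
* **Metabolites**: linear standard-curve inversion
  (`(A - intercept)/slope`; curves require ≥ 3 points and $R^2 \ge 0.95$),
  normalized to protein (screen convention — robust to homogenization
  variability) or to fly number (validation convention — females carry
  more protein, so protein normalization compresses true sex differences).
  Below-blank absorbances clamp to zero with a warning record. Starvation
  utilization is `mean(fed) − mean(starved)` with a bootstrap CI; a
  fractional mode divides by the fed mean.
* **Feeding**: FLIC processing starts from detected contact events;
  events closer than a configurable merge gap (default 5 s) merge into
  meals, and a merged meal's duration spans first to last contact. The
  two-dye choice assay inverts each dye's standard curve and reports the
  yeast preference index `yeast/(yeast + sucrose)`, missing when both
  consumptions are zero.

# What the generators emulate — and what they do not

The gut generator renders a curved tubular midgut as a two-channel 2D
maximum-projection proxy: a natural-cubic-spline centerline of prescribed
arc length (dense polyline integration, 0.25 px steps), nuclei placed by a
Poisson process along arc length (hard-core thinned at 5 px), jittered
transversely, drawn as Gaussian blobs ($\sigma = 1.5$ px) over a dim tube
autofluorescence, with additive Gaussian noise clipped to [0, 1]. The blob
size and spacing are chosen self-consistently: two Gaussian blobs are only
optically resolvable when separated by more than about $2\sigma$, so the
hard-core spacing exceeds that limit. Default male arc length is 1000 px,
which at the effective post-thinning density (~0.5 nuclei/px) and 30% GFP
fraction yields ~150 (male) to ~210 (female) labelled EECs per gut — the
scale of real pan-EEC driver counts — and 15–50 GFP+ cells per decile.
The planted female mid-gut enrichment multiplies the GFP probability in
chosen deciles (default experiments use 2.5× in deciles 3–5, emulating the
female excess of AstC-type cells in the middle midgut).

Not emulated: 3D tile stacks and stitching, photorealistic PSFs and
shading, staining variability between tissues, mating-induced stem-cell
proliferation dynamics, and touching-nucleus clumps beyond what the
hard-core process allows. Passing recovery tests therefore demonstrates
that the measurement chain is unbiased and well-calibrated on tissue-like
geometry with known truth — not that segmentation accuracy transfers to
arbitrary real micrographs.

The screen generator plants one ground-truth effect class per gene ×
trait (null / shared / sex-specific / discordant, the latter with opposite
signs in the two sexes), with magnitudes expressed in SD units of a
knockdown mean (`replicateSd/sqrt(n)`), over an 18-trait panel with
sexually dimorphic control means (females: higher fat and glycogen,
longer stress survival, more feeding, less sleep; glucose nearly
monomorphic) and the replicate structure of the emulated assays (3 vials
for survival, 4 metabolite replicates, 12 FLIC flies, 32 sleep flies).
Optionally it plants a dimorphism-abolishing gene (female means set to
the male control means) and a dimorphism-enhancing gene (each sex pushed
50% further from the other's control). Replicate-to-replicate variance
components are stated assumptions, not measured values.

# Numerical and design choices

* Deciles are 0-based internally (`floor(10t)`, `t = 1` → decile 9);
  human-facing outputs are 1-based.
* All generators are pure functions of `(params, seed)`; cohort members
  derive per-gut seeds from the base seed by fixed affine offsets, and
  generator calls restore the caller's RNG state.
* Ground truth is serialized as JSON side-cars next to 16-bit multi-page
  TIFFs (nuclear channel first); phenotype tables are tidy CSV written
  with 17 significant digits so round trips are bit-exact; activity series
  use the TriKinetics DAMS monitor dialect (42 tab-separated columns, 32
  channel counts per minute row).
* Dendrogram leaf order and merges come from `stats::hclust` on the
  fixed-order dissimilarity, which is deterministic given the inputs.
* Degenerate inputs fail loudly and specifically: non-monotone survival
  counts name the vial, schema violations name the row or trait,
  zero-variance traits are a degenerate-trait error in hit calling and a
  dropped-with-warning column in profile matrices, and a sex with zero
  hits yields a missing fraction.
* `runPipeline()` chains simulate → quantify → assays → screen →
  multivar, writes tidy CSVs plus a JSON manifest (config snapshot,
  package version, per-stage timings and record counts, output checksums),
  and is deterministic given the seed. The demo configuration
  (4 guts/sex at 300–400 px, 25–40 genes) completes in seconds.

# Problem sizes used in the shipped checks

Simulation-backed checks run at the study's stated scale where one is
stated — 165 knockdowns per screen, 10 guts per sex per cohort, 20 flies ×
3 vials, 1440-minute activity days — with 30–200 Monte-Carlo replicates
per stochastic property and 100 replicates for the multivariate recovery.
The no-enrichment decile null (200 cohorts) runs on count-level cohorts
drawn directly at the decile scale; the image path, which is identical
downstream of counting, is exercised by full-image cohorts.

# Known limitations

* The geodesic length is measured on a smoothed pixel path; for extreme
  curvature relative to tube width the path can undercut the true
  centerline slightly. Bounded-curvature tissue keeps this within the 2%
  contract.
* Dunnett T3 p-values assume independent pairwise statistics within the
  studentized maximum modulus family, the standard T3 approximation; a
  Šidák-corrected Welch fallback is trivially obtained from the pairwise
  table.
* Hit-calling behaves as designed only in the sparse-effect,
  precise-control regime described above; screens in which a large
  fraction of knockdowns carry real effects compress z-scores toward zero
  and lose sensitivity, which is a property of the ±SD rule itself.
* The FLIC reducer starts from detected contact events; raw capacitance
  thresholding is delegated to the established FLIC processing convention
  and is out of scope here.
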