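---
title: "Methods: local spontaneous activity, cluster inference, and transcriptome association"
author: "imgtx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local spontaneous activity, cluster inference, and transcriptome association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, the numerical choices, and the known
limitations. The worked numbers in the README are produced by the
`analysis/` drivers and `scripts/acceptance.R`; nothing stated here goes
beyond what those scripts and the test suite compute.

## The analysis in one paragraph

A case-control resting-state fMRI study asks where local spontaneous brain
activity differs between patients and controls, and which genes' cortical
expression profiles co-vary spatially with that difference. The pipeline
computes voxel-wise local-activity metrics (ReHo, ALFF, fALFF) per subject,
compares them between groups with cluster-level family-wise-error control,
processes a donor-brain microarray bundle into a normalized sample-by-gene
matrix, samples the uncorrected group t-map in small spheres at each tissue
sample's MNI coordinate, and correlates every gene's cross-sample expression
with those sampled t-values, keeping Bonferroni-significant genes that also
appear on a GWAS-derived risk-gene list.

## Local activity metrics

**ReHo** is Kendall's coefficient of concordance between a voxel's time
series and those of its 26 neighbours in the surrounding 3x3x3 cube:

W = 12 S / (K^2 (n^3 - n)),  S = sum_i (R_i - mean(R))^2,

where the K series each rank the n time points and R_i is the rank sum at
time point i. Ties get average ranks; no tie-correction term is applied to
the denominator, because ties have measure zero in floating-point data. A
constant series makes W undefined; `kendalls_w()` then returns 0 with a
degeneracy flag, and `reho_map()` counts such voxels. Voxels whose cube is
clipped by the mask or the volume edge use only the available neighbours
(K < 27) so the map's support equals the mask — dropping edge voxels would
silently shrink every cluster that touches the mask boundary.

**ALFF** is the mean single-sided spectral amplitude over DFT bins inside
0.01–0.1 Hz (DC excluded); **fALFF** divides the in-band amplitude sum by
the total non-DC amplitude up to Nyquist and so lies in [0, 1]. The DFT
normalization is fixed once — a_k = 2|X_k|/n, so a unit tone at a bin centre
has amplitude 1 — and every spectral test evaluates a brute-force
periodogram under the same convention.

ReHo is computed on nuisance-regressed, bandpass-filtered data. ALFF and
fALFF are computed on nuisance-regressed data **without** the bandpass: a
band-limited series has all of its power in the band by construction, which
would make fALFF identically 1. The split follows from the definitions; the
ordering of these steps in the original descriptions of the metrics is not
explicit, so this is a documented package decision, not a claim about any
particular prior analysis.

All three maps are divided by their in-mask global mean (mReHo, mALFF,
mfALFF) and then smoothed with a 6-mm-FWHM Gaussian (sigma = FWHM /
(2 sqrt(2 ln 2)) per axis, converted to voxels from the affine; kernel
truncated at 4 sigma and renormalized, zero padding at the volume edge).
Smoothing after standardization matches the convention that smoothing is the
final image-level step.

## Preprocessing

Per subject: discard the first 10 volumes; build a nuisance design with
intercept, linear drift (detrending and nuisance removal in a single OLS
pass, so the drift cannot be re-introduced by a later step), the Friston-24
motion expansion (6 parameters, their one-volume lag, both sets squared),
one indicator column per volume with frame-wise displacement strictly above
0.5 mm (spike regression rather than scrubbing, preserving the temporal
grid), and mean white-matter and CSF signals; regress it out per voxel; then
bandpass 0.01–0.1 Hz by Fourier-domain hard masking. FD follows Power's
definition with a 50-mm rotation radius — the variant the 0.5-mm threshold
presupposes; the formula's variant is otherwise underdetermined. The hard
spectral mask was chosen over an IIR filter because it is idempotent and
exactly characterizable in tests (tones at retained bins pass unchanged).

## Group inference

Voxel-wise pooled-variance two-sample t-tests (df = n1 + n2 - 2), two-sided.
Cluster-level FWE control uses permutation of group labels with the
maximum-cluster-size statistic: threshold the t-map two-sidedly at the
cluster-defining p (default 0.001), group supra-threshold voxels by
26-connectivity (positive and negative exceedances separately, matching the
27-voxel ReHo neighbourhood), and compare each observed cluster's size with
the permutation distribution of the maximum size; p = (1 + #{maxima >=
size}) / (1 + n_perm), which is valid at any permutation count. When the
number of distinct group splits is at most `n_perm` the splits are
enumerated exhaustively. Permutation replaces parametric random-field-theory
correction deliberately: its calibration is testable by simulation inside
this package, whereas RFT's smoothness estimation is not reproducible
without the original software internals.

## Expression processing

The donor bundle is reduced to a normalized matrix in a fixed order:

1. **Intensity filtering** — keep probes above background in at least 50%
   of samples, donors pooled (inclusive at exactly 50%).
2. **RNA-seq-guided probe selection** — per gene, correlate each probe with
   the gene's structure-level RNA-seq reference over matched donor-structure
   units (probe samples aggregated to structure means within the RNA-seq
   donors, pooled across units), drop probes with r < 0.2, keep the best.
   Unit-level aggregation is the resolution at which structure-level RNA-seq
   references exist; correlating raw samples against repeated unit values
   makes the 0.2 rule essentially random at realistic unit counts.
3. **Sample restriction** — left hemisphere AND cortical label AND
   gray-matter mask at the nearest voxel.
4. **SRS normalization** — scaled robust sigmoid, s = 1/(1 + exp(-(x -
   median)/(IQR/1.35))) then min-max to [0, 1]; 1.35 is the
   normal-consistency constant relating IQR to SD. Applied within-sample
   across genes, then within-gene across samples, per donor. The sigmoid is
   strictly monotone, so ranks survive; zero-IQR vectors collapse to 0.5
   with a flag.
5. **Differential stability** — per gene, the mean over donor pairs of the
   Spearman correlation between structure-mean expression vectors over
   shared structures (pairs sharing fewer than 3 structures are skipped);
   keep the top 50% (ties at the cut retained). The regional unit is the
   bundle's structure label; no ontology mapping is attempted.

DS has a consequence worth stating plainly: a gene can track a spatial map
perfectly at sample resolution and still score low DS if the map has no
between-structure variance. Smooth, spatially structured maps (which real
t-maps are) give tracking genes high DS; white-noise maps do not. The tests
use structured maps for recovery checks for exactly this reason.

## Spatial association

The **uncorrected** t-map (not the cluster-thresholded one) is sampled in
3-mm spheres: the mean over in-mask voxels whose centre lies within the
radius (voxel-centre-in-sphere, the simplest exactly testable rule; sphere
membership is inclusive at the boundary). Samples with no in-mask voxel are
flagged and excluded pairwise. Gene-wise Pearson correlations with two-sided
p-values are thresholded at alpha / n_genes (0.05/5013 = 9.974e-6 at the
reference gene count), and the significant set is intersected with the
risk-gene list after upper-casing symbols. The correlation p-values assume
independent samples; spatial autocorrelation of both expression and t-maps
violates this in real data and is reproduced as-is here, deliberately —
spin tests or other autocorrelation-preserving nulls are out of scope.

## Clinical statistics

Group comparisons gate on Shapiro-Wilk normality per group at alpha 0.05
(the gate's alpha is a package choice; only the gate itself is inherited):
pooled t-test when both groups pass, Mann-Whitney otherwise, with the choice
reported. Sex uses Pearson chi-square without continuity correction.
ROI-clinical correlations use Pearson or Spearman by the same gate and are
flagged uncorrected (p < 0.05) and Bonferroni-corrected (p < 0.05/7 = 0.007
for the conventional seven scales). The sensitivity model is an OLS fit of
ROI mean on group plus covariates with a single-df F-test of the group term
by nested-model comparison; covariates that are collinear are dropped with a
warning, and if the covariates already explain the outcome to machine
precision the group F is reported as 0 rather than as a 0/0 ratio. Which
subjects enter a correlation is an explicit argument — the source analyses
vary by scale — and missing values are deleted pairwise with n reported.

## The synthetic-data generator

The generator defines the study conditions under which everything above is
exercised. Defaults: two groups of 15 subjects (group sizes configurable;
the reference cohort is 27 + 30), a 16x16x16 grid of 3-mm voxels centred on
the origin (a desk-scale stand-in for a whole-brain grid), 240 volumes at
TR = 2 s, and concentric synthetic tissue masks (a gray-matter ball with
embedded white-matter and CSF balls).

**BOLD noise** is AR(1) with phi = 0.3 — the simplest model with a
realistically reddened spectrum. **Planted coherence**: group-B subjects
share (within subject) a latent AR(1) series added to every voxel of a
sphere (default radius 7.5 mm, about 56 voxels — the scale of a small
cortical cluster; default centre (-9, 0, 0) mm, left hemisphere). The
mixing weight for a requested effect size d — defined as Cohen's d of the
group difference in **mean in-sphere ReHo** — comes from a frozen pilot
simulation (40 subjects per arm per weight at the default conditions),
interpolated monotonically; the achievable d saturates near 8 where the
latent component starts to dominate between-subject variance, and the
mapping is approximate away from the default geometry and volume count.
**Motion** is a smooth random walk calibrated to a mean FD near 0.1 mm.

A structural fact about this design, established by the pilot: per-voxel
ReHo noise SD is about 3.3x the sphere-mean SD, so a sphere-mean effect of
d = 1.2 corresponds to per-voxel effects near d = 0.37 — far below what a
voxel-wise cluster-defining threshold of p = 0.001 at n = 15 + 15 can
detect (and no generator design can change this: per-voxel d cannot exceed
sphere-mean d). Mean-level calibration and voxel-level detection are
different regimes; tests that plant recoverable clusters therefore use
larger d or looser cluster-defining thresholds, and the recovery study at
d = 1.2 honestly reports low Dice overlap.

**Expression bundles**: sample coordinates are drawn uniformly from in-mask
left-hemisphere (x < 0 mm) voxel centres, with structure labels formed by
compact k-means parcels of the left mask shared across donors (compact
parcels keep the between-structure variance that slab-shaped regions would
average away, which the differential-stability filter depends on); right-hemisphere samples (first two donors
only) and subcortical samples are added as decoys for the restriction step.
Gene baselines are Uniform(6.5, 9.5) on a log-intensity-like scale — the
bounded support keeps the planted intensity-filter margins deterministic at
any gene count. Tracking genes mix the sphere-sampled target map into their
expression at the nominal correlation. Each gene's designated best probe
carries small noise; planted competitors are noisier decoys, anti-correlated
probes (to land below the r = 0.2 cut deterministically), and dim probes at
a fixed low intensity (to fail the above-background filter); every 97th gene
carries only below-threshold probes so probe selection must drop it.
Above-background flags threshold intensity at the 0.2 quantile per donor;
with the default two-probes-per-gene complement the dim fraction stays below
20% so the quantile sits between the dim and normal intensity clusters.

What the generator does **not** emulate: hemodynamic response shape,
physiological (cardiac/respiratory) noise, realistic cortical geometry and
folding, inter-donor expression batch structure, and spatial
autocorrelation of null gene expression. The last one matters: because null
genes are i.i.d. across samples, the association stage's nominal Bonferroni
calibration holds exactly in tests, whereas real expression data are
spatially autocorrelated and the same procedure would be anticonservative.
Passing tests show the machinery is correct under its stated assumptions,
not that the statistical model is adequate for real data.

## Numerical choices and degenerate inputs

* Bandpass/ALFF band membership is inclusive at both edges, consistently.
* Zero pooled variance in a voxel-wise t-test yields t = 0 (flagged), not
  NaN; zero-variance genes get r = NA, p = 1 (flagged).
* Cluster FWE p-values include the observed statistic in the null
  (+1 numerator and denominator), so they are never 0 and remain valid.
* `select_top_ds()` keeps ties at the cut; with all-equal DS everything
  survives.
* Rank-deficient nuisance designs drop dependent columns with a warning
  naming them, rather than failing.
* Sphere sampling with an empty in-mask sphere yields NA; downstream
  correlation drops such samples pairwise.

## Problem sizes used by the tests and the acceptance script

The simulation studies run at the generator defaults (16^3 grid, 240
volumes; 60 volumes and 10 + 10 subjects for null-calibration cohorts),
with 200–500 permutations, 50 null cohorts, 10 recovery seeds, and bundles
of 5013 genes and about 400 retained samples — sizes chosen so the full
suite exercises every stage at the reference gene count while remaining
runnable on a laptop. The acceptance script uses the same conditions at
moderately reduced replication counts; its JSON output records the n used
for each quantity.

## Known limitations

* The permutation FWE replaces the original parametric cluster correction;
  cluster sizes and peak statistics from undeposited subject data are not
  reproducible and are not targets.
* DS is a stand-in at the bundle's structure granularity; the original
  regional matching procedure is not described in enough detail to copy.
* Correlation p-values ignore spatial autocorrelation (see above).
* The coherence-weight calibration is frozen at the default geometry;
  requesting effects at very different grid sizes or volume counts yields
  approximate effect sizes.
* Sphere sampling uses voxel-centre membership, not partial-volume overlap.
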