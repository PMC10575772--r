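---
title: "Methods: outcome subgroups, surface GLMs, RFT cluster inference and transcriptomic decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outcome subgroups, surface GLMs, RFT cluster inference and transcriptomic decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis this package implements

`adaptsurf` implements a longitudinal brain-behaviour analysis for autism
cohorts measured at two timepoints (T1, T2): autistic participants are
stratified by the clinical meaningfulness of their adaptive-behaviour
change, each resulting subgroup is compared vertex-wise to neurotypicals in
cortical surface area (SA) and cortical thickness (CT), cluster-level
inference is carried out with random-field theory (RFT) adapted to
non-isotropic fields on triangulated surfaces, and the resulting difference
maps are decoded against spatial gene expression with gene-set enrichment.
Because the cohort data such analyses run on are access-restricted, the
package ships a seeded synthetic-cohort generator that reproduces the
statistical structure every stage assumes, so the whole chain is testable
end to end.

## Outcome stratification by minimal clinically important difference

Adaptive behaviour is measured by Vineland (VABS-II) age-normed standard
scores (population mean 100, SD 15). The change score is the plain
difference `dV = T2 - T1`; because the scores are age-normed, a child who
improves exactly as expected for their age has `dV = 0`. Classification
uses a minimal clinically important difference (MCID) of 4 composite
standard-score points:

* `dV >= 4` — Increaser,
* `-4 < dV < 4` — No-changer,
* `dV <= -4` — Decreaser.

The boundary values belong to the changer groups; `classify_outcome()`
implements these inequalities literally, and the generator draws each
subject's change from a normal distribution truncated to the label's
interval, so generation and classification are consistent by construction
(the test suite verifies a zero-mismatch round trip). The same classifier
is reused unchanged for alternative stratifications (VABS domain change,
ADOS calibrated-severity change) with a configurable basis column and
threshold; no published MCID exists for ADOS severity scores, so that
threshold is deliberately a config knob with no asserted default
interpretation.

Cohort tables are summarized with one-way fixed-effects ANOVA F statistics
and Pearson chi-squares without continuity correction and without
multiplicity correction, matching the conventions of clinical cohort
tables. `anova_f_from_summary()` recovers F from per-group means, SDs and
ns alone, which lets the package reproduce published table statistics from
printed summaries with no raw data; agreement is limited only by the
rounding of the printed values (about 0.2% for the worst rows).

## Vertex-wise GLMs

Each comparison (one subgroup vs all neurotypicals; or the continuous
change score within autism for the dimensional analysis) is fitted as a
separate ordinary-least-squares model at every vertex — deliberately not
one omnibus model, so each subgroup contrast stands alone. Covariates
follow the feature and analysis type:

| analysis | age basis | extra terms |
|---|---|---|
| T1 | age at T1 (+ age² for CT) | — |
| delta (T2−T1 change) | age at T1 (+ age² for CT) | interval `dT`, age×`dT` |
| T2 | age at T2 (+ age² for CT) | — |

plus sex, full-scale IQ, the total-brain measure matched to the feature
(total SA in cm² for SA; mean CT in mm for CT; toggleable off as a
sensitivity analysis), site as fixed-effect dummies, and optionally a
medication flag. Quadratic age enters for cortical thickness only, whose
developmental trajectory is curvilinear over ages 6–30; surface area is
modelled with linear age.

Numerical choices: continuous covariates are mean-centred within each
fitted model and the quadratic term is the square of the centred age. This
is pure conditioning — the group contrast is unaffected, and the test suite
asserts t-map invariance to affine covariate rescaling at 1e-8. Site
correction via fixed-effect dummies is the simplest linear treatment
consistent with "site-corrected" metrics; the generator plants additive
site offsets so the suite can verify the dummies absorb them. A
rank-deficient design aborts with the collinear columns named. Vertices
with exactly zero residual variance (up to a relative tolerance of 1e-20 on
the response's sum of squares) are flagged and given a 0 / ±Inf sentinel
rather than silently dropped.

Residuals are returned standardized to unit empirical variance per vertex,
which makes the downstream smoothness estimate exactly scale-invariant.

## RFT cluster correction for non-isotropic surface fields

Cluster-forming uses the two-tailed per-vertex threshold `t* =
qt(1 - 0.01/2, df)`; positive and negative suprathreshold components are
extracted separately by edge adjacency and never merged. Local smoothness
is estimated from the standardized residuals: per edge `(i, j)` of length
`L`, the derivative variance is `mean_subjects(((u_i - u_j)/L)^2)`; per
face it is the mean of the three edges; local FWHM is
`sqrt(4 ln 2 / v_f)`; and the face's resel content is
`A_f v_f / (4 ln 2)`. Cluster extents are sums of per-vertex resel shares
(each face contributes a third per member vertex), which measures extent in
smoothness-adjusted units and removes any border tie-breaking ambiguity —
this is what makes the correction valid for non-isotropic fields.

Cluster p-values use the classical Poisson-clumping model: expected cluster
count `m = R rho_2(t*)` from the 2-D t-field Euler-characteristic (EC)
density, expected suprathreshold area `E[A] = R P(T > t*)`, exponential
cluster sizes with mean `E[A]/m`, and
`p = 1 - exp(-m exp(-s / (E[A]/m)))`. Two-tailed inference tests each sign
family at `alpha/2` (default cluster alpha 0.01), keeping cluster signs
interpretable; the reported table carries both the family p and the doubled
two-tailed p. No correction is ever applied across the SA/CT features or
across the three subgroup contrasts — each t-map is corrected over the
surface alone, and the pipeline manifest records this.

**Resolution assumption.** RFT is a continuum theory; on a mesh it is
accurate only when the field is smooth at the scale of a few vertex
spacings. The package's calibration studies therefore fix the mesh so that
FWHM ≥ ~2.5 mean edge lengths for inference (at 10 mm FWHM: an icosphere-4
of radius 30–50 mm, mean edge 2.3–3.8 mm), under which the suite verifies
an empirical null family-wise error rate inside [0.003, 0.03] at nominal
two-tailed 0.01 (1000 null simulations, n = 60 per group). The identity
"expected cluster count = R rho_2(t*)" is sharper: a lattice misses
excursion components smaller than a cell, an O((edge/FWHM)²) loss, so the
suite validates it to Monte-Carlo precision on a finer mesh (FWHM ≈ 9 edge
lengths) and only directionally (within 10%) at inference resolution.
Users supplying their own meshes should respect the same ratio.

## Transcriptomic decoding and enrichment

The unthresholded contrast t-map is reduced to unweighted parcel means over
a k-means parcellation of the (spherical) mesh and correlated with every
gene's parcel-level expression pattern (rows of the atlas standardized to
mean 0, SD 1). Decoding the unthresholded map — rather than the RFT-masked
map — uses the full spatial pattern; the masked option exists in the API
via the corrected map.

Significance per gene comes from a spin test: uniform random 3-D rotations
(quaternion method) are applied to the parcel centroids and each rotated
centroid re-assigned to its nearest original parcel, producing null maps
with the observed spatial autocorrelation. One rotation sequence is shared
by all genes (and all contrasts of a run), preserving gene–gene dependence
under the null, and `p = (1 + #{|r_null| >= |r|}) / (1 + n_spins)`. The
decoded list is the set of genes with Benjamini–Hochberg q < 0.05 over the
spin p-values. A parametric correlation p would be inflated by spatial
autocorrelation; the suite verifies spin-p uniformity under the generator's
null (KS test) and ≥80% recovery of a planted r = 0.8 signal set on a
200-parcel atlas at 500 spins. Note that BH selection imposes a floor: with
`m` genes the smallest attainable spin p, `1/(n_spins + 1)`, must clear
`0.05 k / m`, so `n_spins` should grow with the atlas size (default 1000).

Enrichment of a decoded list against a gene set over the background
universe uses the 2×2 table (`a` decoded∩set, `b` decoded∖set, `c`
set∖decoded, `d` neither), the sample odds ratio `ad/bc` (0 when `a = 0`,
infinite when `bc = 0` with `ad > 0`), and the two-sided Fisher exact
p-value (hypergeometric sum of tables no more probable than observed,
verified against exhaustive enumeration to 1e-12). One BH correction runs
jointly across every contrast-by-set pair of a run. A background
restriction (e.g. to cortically expressed genes) rebuilds the universe and
all margins, as the corresponding sensitivity analysis requires.

# What the synthetic generator emulates — and what it does not

`generate_cohort()` reproduces, at its defaults, the marginal structure of
the reference longitudinal cohort: 161 autistic participants (53
Decreasers, 42 No-changers, 66 Increasers), 172 neurotypicals, baseline age
uniform on 6–30 y, inter-visit interval normal 1.6 ± 0.3 y (truncated below
at 0.25 y), baseline Vineland composite 72.5 ± 12.5, subgroup change
distributions N(−11.23, 8.0), N(0.05, 2.0), N(9.86, 5.5) truncated to their
MCID intervals, FSIQ by diagnosis (101.82 ± 19.8 autistic, 107.05 ± 16.5
neurotypical), per-group female fractions and intellectual-disability
rates, and four acquisition sites with round-robin allocation. Because the
change scores are truncated normals, their realized subgroup means sit at
the truncated-distribution expectation (e.g. about −13.8 for Decreasers),
slightly displaced from the nominal parameters; the printed reference
moments describe already-truncated real data, and matching them exactly
would require inverting the truncation, which the generator deliberately
does not do.

Vertex maps follow
`mu(v) + beta_age (age - 18) + beta_sex (male - 1/2) + site + subject + smooth noise`,
with CT on an absolute scale (mean 2.69 mm, subject SD 0.09 mm, age slope
−0.010 mm/y, sex effect 0.02 mm, site SD 0.03 mm, pre-smoothing vertex
noise SD 0.25 mm) and SA multiplicative about a per-vertex mean scaled so
the map total matches 2293 cm² (relative parameters: subject 9%, age
−0.2%/y, sex 7%, site 2%, vertex noise 25%). Smooth noise is white vertex
noise smoothed to `noise_fwhm` (default 10 mm) by damped neighbour
averaging whose iteration count is calibrated against a point impulse's
second spatial moment — mesh-native, with no volumetric resampling. Total
SA and mean CT per subject are computed from the generated maps, never
drawn separately, so the total-brain covariates are internally consistent.
Planted effects are geodesic discs where one subgroup is shifted by Cohen's
d in units of the per-vertex map SD; T1 effects persist to T2, change and
T2 effects apply at T2 only.

Defaults the reference data do not constrain, chosen once as plausible and
exposed in the spec: medication rates (30% autistic, 2% neurotypical), site
offset SDs, the ADOS T2 drift SD (1.5), and the mesh radius (50 mm — a
sphere of roughly one-hemisphere area whose icosphere-4 edge length
resolves 10 mm fields). Age bands for the age-stratified sensitivity
analysis default to [6, 12), [12, 18), [18, 31).

What passing tests on this generator do **not** show about real data: the
generator has no cortical folding or regional mean structure (maps vary
around a spatially constant mean), no scanner-specific covariance, no
missing visits, no measurement error in the clinical scores, Gaussian noise
throughout, and intellectual disability and medication flags independent of
FSIQ and severity. Calibration and power results transfer to real data only
insofar as the GLM/RFT assumptions (linear covariate effects, smooth
Gaussianish residual fields) hold there.

The expression atlas (`generate_expression_atlas()`) is a synthetic
stand-in for a donor-based transcriptomic atlas: per-gene smooth random
parcel maps, standardized, with designated signal sets mixed as
`r z(map) + sqrt(1-r^2) z(noise)` so each signal gene's correlation with
its target map has expectation `r`. It contains no donor structure, probe
noise, or inter-gene co-expression modules beyond what the shared target
map induces.

# Pipeline, determinism and problem sizes

`run_full_pipeline()` executes the grid (default 3 subgroups × {SA, CT} ×
{T1, delta, T2} = 18 contrasts), decodes every contrast with one shared
spin sequence, and applies one joint BH correction across all
contrast-by-set pairs. All randomness derives from the single config seed
(stage seeds are fixed offsets), outputs are plain text with stable
formatting, and the manifest records config, package version and per-stage
counts — two runs of the same config are byte-identical, which the suite
asserts file by file.

Problem sizes used by the shipped studies, chosen to make each check
statistically decisive at interactive runtimes: GLM calibration at 2562
vertices, n = 120, 200 simulations; FWER calibration at icosphere-4 radius
30 mm, 1000 simulations; EC-count validation at radius 15 mm, 300
simulations; power at radius 50 mm, d = 1.2, n = 50 per group, 100
simulations; decoding on 200-parcel atlases at 500 spins; the end-to-end
determinism run on an icosphere-3 with the full default cohort.

# Known limitations

* Cluster inference inherits the known fragility of RFT at lenient forming
  thresholds; the 0.01 two-tailed default is calibrated here under the
  stated resolution assumption, but permutation inference would be the
  robust alternative on real data.
* The change analysis is a two-visit difference model, not a growth model;
  with more than two visits a mixed-effects approach should replace it.
* The spin test assumes a spherical (or sphere-registered) geometry with
  rotation-invariant sampling; strongly non-uniform parcellations would
  need centroid-weighted variants.
* Decoding defaults (Pearson similarity on the unthresholded map, spin-BH
  q < 0.05 selection) are explicit stand-ins for choices that vary across
  the imaging-transcriptomics literature; both are config-exposed.
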