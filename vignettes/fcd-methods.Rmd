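---
title: "Functional connectivity density mapping: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional connectivity density mapping: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcdmap)
```

# The method

Functional connectivity density (FCD) mapping asks, for every voxel of a
resting-state BOLD acquisition, how strongly that voxel is coupled to the
rest of the brain. For voxel $i$ with in-mask partners $j$,

$$\mathrm{FCD}(i) \;=\; \sum_{j \neq i,\; r_{ij} > r_{thr}} r_{ij},$$

where $r_{ij}$ is the Pearson correlation of the preprocessed time series
and $r_{thr} = 0.25$ by default. This is a *weighted* degree (a sum of
suprathreshold correlation values), not a binary partner count; only
positive suprathreshold correlations contribute, which keeps the maps
non-negative, and the self-correlation is always excluded. The sum is split
by the Euclidean distance between voxel centers:

* **local FCD (lFCD)** — partners within 3 mm (on a 3 mm isotropic grid,
  the sphere holds the seed plus its 6 face neighbors, 7 voxels in all);
* **distant FCD (dFCD)** — partners beyond 25 mm;
* the 3–25 mm band is deliberately assigned to *neither* index, so local
  and distant connectivity can never overlap. The package computes this gap
  sum explicitly, so `local + gap + distant = total` is an exact invariant
  checked per voxel rather than a definition.

Each subject's maps are normalized by the global (in-mask) mean density and
smoothed with an 8 mm FWHM Gaussian kernel before group analysis. Group
inference is a voxel-wise one-way ANOVA across control, non-HE and MHE
cohorts with age, sex and education residualized out beforehand, followed by
post-hoc two-sample t contrasts inside the ANOVA-significant regions.
Cluster-extent correction uses a Monte-Carlo null in the AlphaSim style.
Regional mean FCD values from the surviving ANOVA clusters are correlated
with clinical scores (NCT-A, DST, blood ammonia) by partial Spearman
correlation — midranks, covariates regressed out of both rank vectors —
with a Bonferroni cutoff of $\alpha$ divided by the number of regions
tested.

# Key parameters

| parameter | default | unit | role |
|---|---|---|---|
| `r_threshold` | 0.25 | — | minimum correlation entering a density sum |
| `local_radius_mm` | 3 | mm | lFCD sphere (7 voxels at 3 mm isotropic) |
| `distant_radius_mm` | 25 | mm | dFCD exclusion radius |
| `low_hz`, `high_hz` | 0.01, 0.08 | Hz | ideal bandpass passband |
| `n_discard` | 10 | volumes | signal-equilibration scans dropped |
| `smooth_fwhm_mm` | 8 | mm | Gaussian kernel for group analysis |
| `voxel_p` | 0.05 | — | voxel-level threshold before clustering |
| `alpha` | 0.05 | — | family-wise cluster level |
| `connectivity` | 18 | — | cluster connectivity (faces + edges) |
| `max_trans_mm`, `max_rot_deg` | 1.0 | mm, ° | strict motion-exclusion limits |

The voxel-level threshold before cluster correction is set to 0.05 — the
most literal reading of a corrected $P<0.05$ analysis — and is exposed in
the configuration, as are all of the above (`fcd_config()`).

# Preprocessing contract

The per-subject pipeline is fixed in order: discard initial volumes →
per-voxel linear detrend → bandpass → nuisance regression. The bandpass is
an ideal (boxcar) DFT filter: bins with $0.01 \le f \le 0.08$ Hz are kept
exactly, everything else (including DC) is zeroed. This mirrors the classic
resting-state toolboxes, gives an exactly testable contract (in-band
sinusoids pass untouched, out-of-band ones vanish, the filter is
idempotent), and makes "filtering preserves the planted structure" provable
for the synthetic generator. Nuisance regressors are an intercept, the six
rigid-body motion parameters, mean CSF and white-matter signals where masks
are supplied, and optionally the global mean. Nuisance means are computed
from the *post-bandpass* data — the alternative (regressing unfiltered
nuisance signals) differs only in out-of-band components the filter has
already removed from the data. Global-signal regression defaults to on,
matching common practice, but is a flag because the step is genuinely
contested (and see the validation section for a concrete reason).
Masked-out voxels are never modified and never contribute to nuisance
means. Framewise displacement uses the Power convention: the sum of
absolute backward differences of the six parameters with rotations mapped
to arc length on a 50 mm sphere; the reference formulation counts spikes
without fixing a formula, so the convention is stated here.

# The synthetic cohort generator

No patient imaging data are distributed with studies of this kind, so every
stage is validated against a seeded generator whose correlation structure
is known in closed form. A *hub* is a seed voxel plus its neighborhood
within `region_radius_mm`. Member voxels of hub $h$ (with pair latent $v_p$
and region latent $u_h$, all unit-variance band-limited Gaussian series)
are

$$x = \sqrt{c_d}\, v_p + \sqrt{c_l - c_d}\, u_h + \sqrt{1 - c_l}\,\varepsilon,$$

so that the pairwise correlation is exactly $c_l$ within a region and
$\sqrt{c_{d,i} c_{d,j}}$ between members of paired regions, with the
feasibility constraint $c_d \le c_l \le 1$ enforced after group multipliers
are applied. Background voxels are independent noise. All components are
band-limited inside 0.01–0.08 Hz (synthesized directly in the frequency
domain), so the bandpass stage is transparent to the planted structure and
the closed-form correlations survive preprocessing. Group effects are
multipliers: a shared local-coupling deficit for both patient groups, and
MHE-only distant multipliers with opposite directions for "cortical"
(decrease) and "subcortical" (increase) hub pairs, mimicking the reported
redistribution of long-range connectivity toward thalamus and caudate. The
study reports no effect sizes in FCD units, so the default multipliers
(local 0.6; distant subcortical 1.8, cortical 0.5) are generator choices,
not estimates.

Phenotypes are drawn from normal distributions: controls use the published
control summaries (NCT-A $44.06 \pm 10.66$ s, DST $46.83 \pm 12.51$); the
two patient groups use means/SDs chosen so that their 69/34 mixture
reproduces the published all-patient summaries ($54.38 \pm 20.02$ s and
$35.52 \pm 11.80$; the mixture gives $\approx 54.3 \pm 17.6$ and
$\approx 35.4 \pm 10.9$). The MHE rule — abnormal beyond two control SDs on
at least one test — is read one-sided in the impaired direction of each
test (NCT-A is a completion time, so high is worse; DST is a score, so low
is worse), with strict inequalities. Motion traces are slow random walks
(0.02 mm / 0.02° per volume) with optional injected spikes; per-subject
streams all derive from one root seed, so any subject is reproducible in
isolation.

What the generator does *not* emulate: hemodynamic response shapes,
physiological (cardiac/respiratory) noise, scanner drift beyond a linear
trend, spatial autocorrelation of the background, and the pervasive
long-range correlation structure of real brains (its background is
spatially white). Passing tests therefore demonstrate correctness of the
computations and calibration of the inference under the stated model — not
that the biological conclusions of any particular study are right.

# Cluster-extent correction and its null model

`monte_carlo_extent_threshold()` implements the classic recipe: fill the
mask with unit Gaussian noise, smooth to the nominal FWHM
(mask-renormalized, exactly as the data are smoothed), re-standardize,
threshold at the upper `voxel_p` quantile, record the largest connected
component; the extent threshold is the smallest $k$ whose exceedance
fraction is at most `alpha`.

Applied verbatim to ANOVA F maps, that single-Gaussian-field null is
systematically *mis*calibrated: an F statistic built from $N$ smoothed
component fields has an effectively rougher spatial correlation than its
components (for the numerator quadratic form the autocorrelation is
approximately the square of the component autocorrelation, i.e. an
effective FWHM reduced by $\sqrt 2$). Empirically, on 500 effect-free
synthetic cohorts the Gaussian null at the applied 8 mm kernel yields a
family-wise rate near 0.01 (conservative), while the $\sqrt 2$-corrected
smoothness overshoots to about 0.09 — neither acceptable. The package
therefore adds `null_model = "anova"`: each iteration simulates the
statistic field actually tested (one smoothed Gaussian map per subject,
random nuisance covariates consuming the same degrees of freedom, the
voxel-wise F across the real group structure, thresholded at its own upper
`voxel_p` quantile). This matches the test by construction; the
package-level calibration experiment (`null_calibration()`, 500 cohorts of
3 × 8 subjects on a 12-voxel cube with 100 volumes, 1000 Monte-Carlo
iterations) lands the family-wise rate inside the binomial 95% band around
0.05. The classic Gaussian model remains the default of the exported
function; the pipeline passes the ANOVA-field model explicitly.

Cluster peaks are reported at the voxel with the largest absolute
statistic, ties broken at the lowest linear index (determinism); extents
are reported in voxels and mm³ (voxel volume 27 mm³ at 3 mm isotropic).

# The planted-pattern recovery experiment

`pattern_recovery()` asks whether the full pipeline reproduces the
qualitative finding pattern from planted effects: local deficits in both
patient groups versus controls with *no* local difference between the
patient groups, and a distant increase only in the MHE-versus-others
contrasts at the subcortical pair. Four design points matter, all learned
from the structure of the problem rather than tuned to an outcome:

1. **Region size.** Planted regions use a 6 mm radius (33 voxels): a
   single-voxel effect diluted by an 8 mm kernel cannot reach the ~50-voxel
   extent thresholds that a 2744-voxel mask demands.
2. **No normalization inside the experiment.** On these sparse synthetic
   maps the global-mean divisor is dominated by the planted regions
   themselves, so dividing by it (per-map or total) cancels the planted hub
   differences and simultaneously creates an opposite-signed whole-brain
   offset between groups — a normalization artifact, not a pipeline bug.
   The generator already produces scale-calibrated subjects, so raw maps
   are the clean substrate. (On real data, where the divisor is dominated
   by pervasive true connectivity, normalization serves its intended role
   of removing per-subject scale.)
3. **No global-signal regression.** With planted shared latents the global
   mean is itself group-dependent; regressing it out leaks the planted
   couplings into diffuse secondary group differences — the textbook GSR
   artifact, and a concrete illustration of why the flag exists.
4. **Site attribution by peak proximity.** A contrast "appears at" a
   planted site when a surviving cluster's peak lies within one smoothing
   FWHM of the site. Smoothing legitimately displaces statistic peaks into
   the low-variance halo just outside a planted region, while requiring
   peak proximity keeps whole-mask false-positive clusters from being
   attributed to a site they merely touch. The same rule applies to
   expected and null contrasts.

Effect sizes are documented above (multipliers 0.6 / 1.8), groups of 10,
250 volumes per subject. With 50 replicates the expected pattern is
recovered in well over 80% of cohorts; the residual failures are dominated
by occasional extent-corrected false positives in the null contrasts, at
the rate the correction is designed to allow.

# Numerical choices and degenerate inputs

* Correlations are computed from standardized series in voxel blocks of
  bounded size (never materializing the full correlation matrix); results
  are block-size-independent to ~1e-15 and are checked elementwise against
  a naive all-pairs oracle in the tests. The kernel visits each unordered
  block pair once (correlation symmetry).
* Zero-variance in-mask voxels make correlation undefined; `compute_fcd()`
  refuses them by name and instructs removal from the mask.
* Normalization requires a positive in-mask mean; an all-zero map (e.g. a
  distant map on a grid smaller than the distant radius) is an error, not
  a silent division by zero.
* Smoothing is separable, mask-renormalized (smoothed map divided by the
  smoothed mask), so constants are preserved exactly and brain-edge voxels
  are not attenuated; `fwhm = 0` is the identity. Kernels are truncated at
  3.5 SD.
* The one-sample t at zero-variance voxels returns the degenerate limit
  (p of 0 or 1) with a warning rather than NaN.
* Covariate adjustment is pre-residualization (residuals plus grand
  intercept) with the consumed degrees of freedom charged to the error
  term: F has df $(k-1,\; N-k-c)$, post-hoc t has $n_1+n_2-2-c$.
* Partial Spearman uses midranks for ties and the t approximation with
  df $= n-2-c$; an exact permutation p-value is available for small
  samples.
* Rank-deficient nuisance or covariate designs are rejected with the
  collinear columns named.

# Known limitations and open readings

* The per-map versus total-map normalization divisor is genuinely
  ambiguous in the method's verbal description; per-map is the default and
  both are implemented (`normalize_fcd(divisor=)`).
* One-sample t maps are assumed to use the same cluster-correction
  machinery as the group contrasts.
* Smoothness for the Gaussian null defaults to the applied kernel;
  residual-smoothness estimation is out of scope (and the ANOVA-field null
  sidesteps the question for the group analyses).
* The published cohort table's education comparison (p = 0.82) is not
  reproducible from its own printed summaries ($10.97 \pm 3.18$ vs
  $10.45 \pm 3.11$, $n = 103$ each give $p \approx 0.24$ under a pooled or
  Welch t); the education row is therefore not used as a numeric check.
* Problem sizes in the validation experiments (12–14-voxel cubes, groups
  of 8–10, 100–250 volumes, 500/50 replicates) are chosen so the full
  suite runs on a single desk-scale core; they are stated here as the
  package's validation conditions.
* Rigid-body realignment, slice-timing correction, spatial normalization
  and anatomical labeling are out of scope: images are assumed on a common
  grid and motion parameters are inputs.

# Reading the outputs

`run_pipeline()` writes, per map type, the ANOVA cluster table
(`anova_*FCD_clusters.csv` with peak mm coordinates, extents in voxels and
mm³, peak F), post-hoc contrast maps in memory, regional correlation
tables (`correlations_*FCD_<group>.csv` with rho, uncorrected p, the
Bonferroni cutoff and both significance flags), the cohort comparison
table (`table1.csv`), the subject table with motion summaries, the exact
configuration (`config.yaml`) and a provenance log (package version, seed,
configuration hash, extent threshold). Re-running with the same
configuration and seed reproduces every output byte-identically.
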