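---
title: "Methods: connectivity-based parcellation of the globus pallidus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity-based parcellation of the globus pallidus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pallidoparc)
```

# The model

Connectivity-based parcellation (CBP) subdivides a seed structure by asking,
for every voxel, which remote target it is most strongly connected to. The
evidence is a set of track-density volumes: for each target, a nonnegative
scalar image counting streamline visits per seed voxel. `pallidoparc`
implements the hard-segmentation variant of CBP used for the pallidal
segments:

1. **Normalization.** Each density map is divided by its mean in-ROI
   intensity so that maps of targets with very different total streamline
   counts become comparable. By default the mean is taken over *strictly
   positive* in-ROI voxels: a map that reaches only part of the seed should
   not have its surviving values inflated merely because its many zero
   voxels drag the mean down. The alternative convention (mean over all ROI
   voxels) is exposed as `meanMode = "all"` in `normalizeDensity()` for
   regression comparisons, since descriptions of the procedure do not
   always pin this down.
2. **Winner-takes-all.** Each voxel with at least one strictly positive
   density receives the label of the map with the largest normalized value.
   Voxels with no positive evidence under any target stay unlabeled (0):
   attribution presumes evidence of connectivity. Exact ties are broken by
   the lowest target index under the fixed anterior-to-posterior ordering
   (limbic, associative, sensorimotor, other) — deterministic, documented,
   and exercised explicitly in the tests.
3. **Two stages.** Relay nuclei (striatum, subthalamic nucleus, thalamus)
   are first parcellated by their cortical connectivity into four
   functional groups; the pallidal segments are then parcellated against
   density maps whose targets are those stage-1 clusters, pathway by
   pathway. GPi is analysed against three pathways (striatopallidal,
   subthalamopallidal, pallidothalamic) and GPe against two, so the full
   design yields $3 \times 4 = 12$ GPi and $2 \times 4 = 8$ GPe cluster
   maps. Tractography itself (seeding, step, angle, cutoff) is upstream of
   this package; those parameters are carried as provenance metadata only.
4. **Group maps.** Subject parcels are binarized and averaged into per-label
   probability maps; a population threshold retains voxels covered in at
   least a fraction $\theta$ of the sample ($\theta = 0.5$ by default, with
   an *inclusive* comparison so "at least half" means exactly that).
   Volumes ($n_\mathrm{vox} \times |\det A|$ for voxel-to-world affine $A$)
   and centers of gravity (unweighted centroid of the binary mask, mapped
   through the affine) summarize each map. The probability-weighted
   centroid is available as an option of `centerOfGravity()` for
   sensitivity checks, but the default matches the convention of reporting
   the COG of the *thresholded* (binary) map.

Because per-label group maps are thresholded independently, maps of
different labels may overlap at the group level even though each subject's
parcellation is exclusive; the test suite contains a constructed example.

# The statistical surface

**Overlap.** For binary maps $A,B$ the Dice coefficient is
$D = 2|A \cap B| / (|A| + |B|)$ and the Tanimoto coefficient
$T = N(A \cap B)/N(A \cup B)$; they are linked by $D = 2T/(1+T)$, asserted
as a property on random fixtures. Reproducibility across $S$ subjects uses
all $m = \binom{S}{2}$ unordered subject pairs with the inverse-size weight
$\alpha = 2/(|A|+|B|)$:

$$\mathrm{OBL} = \frac{\sum_m \alpha_i N(A_i \cap B_i)}
                      {\sum_m \alpha_i N(A_i \cup B_i)}, \qquad
  \mathrm{TAO} = \frac{\sum_m \sum_{i=1}^{n} \alpha_i N(A_i \cap B_i)}
                      {\sum_m \sum_{i=1}^{n} \alpha_i N(A_i \cup B_i)}.$$

$\alpha$ is undefined when a parcel is empty in both subjects of a pair;
such pairs are excluded from both sums (not treated as $0/0$) and the
count of skipped pairs is reported. Dice is computed between
50%-thresholded *group* maps of different pathways, whereas OBL/TAO operate
on *subject-level* parcels — both entry points are exposed because the two
comparisons answer different questions (spatial coherence across pathways
vs reproducibility across subjects).

**Laterality.** Each parcel's streamline density index is
$\mathrm{SDI} = 100\,v/V_\mathrm{ROI}$ (percent of the seed ROI).
Left-right asymmetry is tested with a paired sign-flip permutation test:
the observed statistic is the paired $t$ on $d = \mathrm{left} -
\mathrm{right}$ per variable; under the null each subject's whole
difference vector flips sign with probability $\tfrac12$, the same flips
applying to all variables of a permutation so that cross-variable
correlation is preserved; each permutation contributes $\max_j |t_j|$, and
the corrected two-sided p-value is the add-one Monte-Carlo estimator
$(1 + \#\{t^{\max} \ge |t_j^{obs}|\})/(n_\mathrm{perm}+1)$, which cannot
return 0. The correction family is the set of variables within one
(nucleus, pathway) parcellation — four labels — matching a per-analysis
correction; the family is whatever columns are passed, so a joint family
is available by binding matrices. With `exact = TRUE` all $2^n$ sign
patterns are enumerated (plain proportions, no add-one). Variables with
zero-variance differences and nonzero mean have undefined $t$; they are
excluded from the max with a warning, while all-zero difference vectors
yield $t = 0$ and $p = 1$. Subject-level dominance uses
$\mathrm{LI} = (\mathrm{Left}-\mathrm{Right})/(\mathrm{Left}+\mathrm{Right})$
with *strict* cutoffs: left-lateralized iff $\mathrm{LI} > 0.1$,
right-lateralized iff $\mathrm{LI} < -0.1$.

**Proximity.** Stimulation sites are mm-space points; membership in a map
uses the inverse affine with nearest-voxel rounding (sites are points and
masks binary, so no partial-volume interpolation), and reports rank maps by
Euclidean COG distance. Site tables carry a provenance tag per row; real
stimulation coordinates are input data, never constants baked into code.

# The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
with ground truth known by construction. The seed ROI is an axis-aligned
ellipsoid — connected and convex like a pallidal segment mask — on a grid
of 1 mm template voxels, default half-axes 6/13/5 mm (≈1.6 cm³, the scale
of the combined pallidal segments, 26 mm anteroposteriorly). Target $t$'s
density at voxel $v$ for subject $s$ is

$$\mathrm{dens}_t(v) = G_t\!\big(p(v) + \delta_s\big)\,\varepsilon_{t}(v),
  \qquad G_t(p) = \exp\!\left(-\frac{(p-c_t)^2}{2w^2}\right),$$

where $p(v) \in [0,1]$ is the voxel's normalized position along the
gradient axis, $c_t$ are strictly increasing peak positions
(0.15/0.40/0.65/0.90 by default, giving the anterior limbic → posterior
"other" ordering), $\delta_s \sim N(0, \sigma_\mathrm{jitter})$ is a
subject-level rigid translation of the profiles (the ROI itself stays
fixed, matching a template-space group analysis), and $\varepsilon$ is
i.i.d. log-normal with unit mean and coefficient of variation
`noiseCV` — multiplicative because track densities are nonnegative
counts-like quantities. Defaults: `noiseCV = 0.3`,
`jitterSDmm = 0.5` (half a voxel), `rngSeed` making the whole cohort
reproducible.

**Ground truth.** The truth label field is the winner at each voxel of the
*mean-normalized* noiseless, jitter-free profiles — i.e. exactly what the
segmentation of an ideal noise-free subject produces. Normalization
matters here: dividing each profile by its in-ROI mean preserves the
contiguous-slab structure (log-ratios of two Gaussians remain monotone
along the gradient) but shifts boundaries slightly relative to the raw
argmax, because edge territories have smaller in-ROI means than interior
ones. Defining truth after normalization makes the noiseless
identities exact: with zero noise and zero jitter, every subject's
parcellation, and hence the 50% MPM of every label, equals the truth
parcel, and OBL = TAO = 1 — all asserted in the tests.

**Geometry as an error budget.** Two mechanisms corrupt recovery under the
default conditions. Sub-voxel jitter translates all boundaries together;
on a discrete lattice a boundary crossing a plane of voxel centers flips
that whole plane, so the expected error is roughly (number of boundaries)
× (expected planes crossed) × (plane fraction of the ROI). Voxel noise
mislabels a band around each boundary whose width scales with
$w^2/\Delta c$ (the inverse log-ratio slope). The defaults — 26 voxels
across the gradient (plane fraction ≈ 4%) and profile width $w = 0.06$
(slope steep enough that the noise band is a fraction of a voxel) — put the
expected per-subject error near 7%, and the cohort-mean recovery observed
under the standard conditions (20 subjects, CV 0.3, half-voxel jitter) is
92–95% across seeds. Recovery is asserted on the cohort mean: a single
subject drawn in the jitter tail (e.g. a 1.5-voxel shift) can legitimately
fall below 90% while the generator is behaving exactly as specified. A
related subtlety: at fixed jitter, *small* amounts of voxel noise can
slightly *raise* mean recovery, because noise re-randomizes planes that
jitter flipped wholesale and about half of those voxels fall back to the
true label; the monotonicity check therefore carries a two-point
Monte-Carlo tolerance.

**Planted asymmetry.** Left/right cohorts are generated independently with
a shared geometry. A pure per-map amplitude offset cannot plant a
hemispheric effect — mean-intensity normalization divides it out exactly
(that scale invariance is itself a tested property). The plant is instead
a per-target profile *width* multiplier for the left hemisphere
(`leftWidthMult`): widening one target's profile moves the
winner-takes-all boundaries outward, enlarging that parcel and raising its
SDI, an effect that survives normalization. Planting on an interior
territory (associative) is most powerful because interior parcel sizes are
first-order insensitive to jitter. The corrected p-value for the planted
label falls monotonically as the multiplier grows (tested over 1.0 / 1.4 /
1.8 at 16 subjects).

**What the generator does not emulate.** Real tractography noise is
spatially correlated, anisotropic and subject-specific; real territories
are not perfect slabs, registrations are imperfect, and densities exhibit
distance and curvature biases. Passing tests therefore demonstrate the
*correctness of the statistical machinery* under a controlled model, not
the anatomical validity of any particular parcellation of real data.

# Numerical and interface choices

* Voxel indices are 0-based against the NIfTI RAS affine; all reported
  coordinates are mm in template space. Affines are carried explicitly on
  every object and written into NIfTI sform/qform on export.
* The population threshold uses `fraction >= threshold - 1e-12`; fractions
  are ratios of small integers, and the slack only guards against the
  representation of values like $1.5/3$.
* Permutation t statistics are computed from flipped means only, using the
  sign-flip invariance of $\sum d^2$; degenerate permutations with zero
  flipped variance and zero mean contribute $t = 0$. Tie comparisons use a
  $10^{-8}$ tolerance so the identity permutation always counts.
* Exact enumeration is limited to $n \le 20$ subjects ($2^n$ patterns).
* RNG is always confined: every stochastic function takes a seed, derives
  child seeds below $2^{31}$ for sub-simulations, and restores the
  caller's RNG state afterwards.
* Problem sizes in the shipped tests and acceptance script (grids of
  ~1,700-voxel ROIs, 3–20 subjects, 2,000–50,000 permutations, 500 null
  replicates) were chosen so the full suite completes in well under a
  minute while keeping every Monte-Carlo comparison inside stated
  tolerances; all scale linearly if larger checks are wanted.

# Known limitations

* Only the simulate mode of `runPipeline()` is wired end-to-end; external
  data enter through `readCohort()`/`validateManifest()` and the module
  functions, which accept any co-registered NIfTI volumes on one grid.
* No soft or threshold-based alternative segmentation is provided — the
  hard winner-takes-all rule is the implemented contract, and unlabeled
  voxels are the only expression of uncertainty.
* Subject-to-template registration is out of scope: all inputs must
  already live on one grid, and `validateManifest()` enforces this rather
  than resampling.
* Comparisons against the publicly deposited pallidal group maps require a
  separate download; the regression test reports a failure when the maps
  are not present locally.
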