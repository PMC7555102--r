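# pallidoparc

Connectivity-based parcellation (CBP) and group mapping of the globus
pallidus in R.

The internal (GPi) and external (GPe) pallidal segments are organized into
limbic, associative and sensorimotor territories arranged along the
anteroposterior axis, and the GPi sensorimotor territory is the surgical
target for pallidal deep brain stimulation in dystonia. Diffusion
tractography can recover this topography: for each seed voxel one counts
streamline visits to each remote target (a track-density map), and a
*winner-takes-all* rule assigns the voxel to the target with the highest
normalized density. `pallidoparc` implements this hard-segmentation
pipeline in two stages — relay nuclei (striatum, subthalamic nucleus,
thalamus) are first parcellated by cortical connectivity, and the pallidal
segments are then parcellated against the resulting functional clusters
through the striatopallidal, subthalamopallidal and pallidothalamic
pathways — together with the complete statistical surface used to evaluate
such parcellations:

* **Segmentation core** — mean-intensity normalization of density maps
  (`normalizeDensity`), exclusive winner-takes-all labeling with
  deterministic tie-breaking (`winnerTakesAll`), and the chained two-stage
  design (`twoStageParcellate`), yielding 12 GPi and 8 GPe cluster maps in
  the full four-territory configuration.
* **Group maps** — per-label probability maps across subjects
  (`buildProbabilityMap`), maximum probability maps retaining voxels
  covered in at least half of the sample (`thresholdMPM`), volumes and
  centers of gravity in template mm coordinates (`maskVolume`,
  `centerOfGravity`).
* **Overlap statistics** — Dice `D = 2|A∩B|/(|A|+|B|)` between
  functionally homologous maps; Tanimoto `T = N(A∩B)/N(A∪B)`; and the
  size-weighted groupwise reproducibility measures
  `OBL = Σ_m α N(A∩B) / Σ_m α N(A∪B)` (per cluster, over all unordered
  subject pairs, with `α = 2/(|A|+|B|)`) and TAO (the same double sum
  accumulated over all clusters of a parcellation).
* **Laterality** — streamline density index `SDI = 100·v/V_ROI` per
  parcel, lateralization index `LI = (Left−Right)/(Left+Right)` with ±0.1
  dominance cutoffs, and a paired sign-flip permutation test with *t*-max
  familywise correction (`pairedPermutationTmax`).
* **Stimulation-site proximity** — Euclidean distances between map centers
  of gravity and named stimulation coordinates, site-in-map membership and
  nearest-map rankings (`proximityReport`).
* **Synthetic cohorts** — a generator (`simulateCohort`,
  `simulateTwoStagePallidal`, `simulateBilateralCohort`) producing
  multi-subject density maps with an anteroposterior Gaussian topography,
  multiplicative log-normal noise, subject-level jitter and an analytically
  known ground-truth label field, so every component is testable against
  known answers.

Volumes are exchanged as NIfTI (via RNifti), cohorts and runs are described
by YAML manifests, and all metric tables are plain CSV.

## Worked example

Simulate an eight-subject cohort, parcellate every subject, build 50%
maximum probability maps, and relate the sensorimotor map to a synthetic
stimulation site:

```r
library(pallidoparc)
cfg <- cohortConfig(nSubjects = 8)
coh <- simulateCohort(cfg)
parcels <- lapply(subjects(coh),
                  function(s) parcellateSubject(subjectDensities(s)))
mean(sapply(parcels, labelRecovery, truth = truthParcellation(coh)))
#> [1] 0.917
gm <- buildGroupMaps(parcels, thresholdFraction = 0.5)
mpmTable(lapply(gm, `[[`, "mpm"), nucleus = "GPi",
         pathway = "striatopallidal", hemisphere = "right")
#>   nucleus         pathway        label hemisphere n_voxels volume_mm3  cog_x  cog_y  cog_z
#> 1     GPi striatopallidal       limbic      right      332        332  0.045 -8.127  0.006
#> 2     GPi striatopallidal  associative      right      595        595 -0.008 -2.545 -0.013
#> 3     GPi striatopallidal sensorimotor      right      565        565 -0.013  3.077  0.012
#> 4     GPi striatopallidal        other      right      290        290  0.007  8.500  0.000
as.numeric(totalAccumulatedOverlap(parcels))
#> [1] 0.855
sites <- makeSiteTable(coh, labels = "sensorimotor")
cogs <- data.frame(name = "striatopallidal",
                   t(centerOfGravity(gm$sensorimotor$mpm)))
proximityReport(cogs, sites)
#> ProximityReport: 1 maps x 2 sites (mm)
#>                 site_sensorimotor site_offset_probe
#> striatopallidal              0.74              5.62
```

Reading the output: 91.7% of seed voxels per subject are assigned their
generating territory despite 30% voxel noise and half-voxel jitter; the
four 50%-threshold MPMs are ordered anterior (limbic, COG y ≈ −8 mm) to
posterior (other, y ≈ +8.5 mm); the groupwise TAO of 0.855 quantifies
between-subject reproducibility of the whole parcellation; and the
sensorimotor map's center of gravity lies 0.74 mm from the site placed at
the true sensorimotor centroid (and 5.62 mm from a probe site offset from
the limbic centroid).

The full end-to-end analysis — bilateral two-stage simulation,
parcellation, MPMs, Dice/OBL/TAO tables, SDI lateralization with the
permutation test, and proximity reports — is one call:

```r
runPipeline(list(cohort = list(nSubjects = 10), seed = 7), outDir = "run")
```

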