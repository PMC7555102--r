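Package: pallidoparc
Title: Connectivity-Based Parcellation and Group Mapping of the Globus Pallidus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage connectivity-based parcellation (CBP) of the internal
    and external globus pallidus from tractography-derived connectivity
    density maps, together with its complete statistical surface:
    winner-takes-all hard segmentation of normalized density maps, group
    maximum probability maps with population thresholding, Dice/Tanimoto
    overlap statistics and their size-weighted groupwise variants (OBL, TAO),
    streamline density indices with lateralization statistics and a paired
    sign-flip permutation test using t-max familywise correction, and
    spatial-proximity analysis of parcel centers of gravity against deep
    brain stimulation coordinates. A synthetic multi-subject cohort generator
    with analytically known ground-truth labels supports validation of every
    component.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'pallidoparc-package.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'syntheticCohort.R'
    'cbpEngine.R'
    'groupMaps.R'
    'similarityMetrics.R'
    'lateralityStats.R'
    'stimProximity.R'
    'ioPipeline.R'
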