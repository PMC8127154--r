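Package: silentstar
Title: Simulation and Reliability Analysis of Near-Silent Multi-Echo Radial fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end synthetic-data pipeline contrasting a near-silent
    multi-echo 3D radial ("Looping Star" style) fMRI acquisition with a
    conventional single-echo EPI-style acquisition during an auditory oddball
    task. Provides oddball event-schedule generation with spacing constraints,
    a labelled digital head phantom with a TE-dependent BOLD signal model,
    segmented 3D radial k-space sampling with dead-time centre reacquisition,
    density-compensated nearest-neighbour gridding reconstruction, optimal
    multi-echo combination, temporal-SNR mapping, event-related GLM analysis
    with a canonical double-gamma HRF and AR(1) prewhitening, sign-flip
    permutation cluster inference, and voxel-wise ICC(3,1) test-retest
    reliability maps with intra-voxel reliability summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
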