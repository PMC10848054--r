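Package: thalamod
Title: Modular Network Analysis of Thalamocortical Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the modular architecture of resting-state
    functional brain networks and the role of the thalamus within them.
    Implements temporal preprocessing of parcel time series (detrending,
    band-pass filtering, nuisance regression, motion-based exclusion),
    construction of Pearson connectivity matrices with proportional sparsity
    thresholding and area-under-curve summarization, fixed-partition
    modularity Q and modular segregation indices, winner-take-all functional
    parcellation of thalamic voxels into seven cortical networks, two-step
    thresholded thalamocortical networks with participation coefficient and
    within-module degree z-score hub metrics, and the accompanying
    group-comparison and correlation statistics. A synthetic cohort
    generator with planted modular structure provides ground truth so the
    entire analysis runs and is testable without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    RNifti,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
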