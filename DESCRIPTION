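Package: veingraph
Title: Identification of Venous Voxels in Resting-State fMRI via
    Connectivity Graph Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies voxels in BOLD fMRI time series that are dominated
    by macrovascular (venous) signal rather than local neuronal activity.
    A voxelwise Pearson correlation graph is built over all in-brain voxels
    of a band-pass filtered 4D series, binarized at the largest absolute
    correlation threshold for which the sparsity statistic
    S = log(E)/log(K) stays below a bound, and clustered by fast-greedy
    modularity optimization; all communities of 50 or more voxels are
    pooled into a venous-voxel mask. Includes validation utilities
    (overlap with an SWI-derived vein mask, brain-edge definition by 3D
    box erosion, temporal standard-deviation comparison, seed correlation
    maps) and a synthetic phantom generator with ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
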