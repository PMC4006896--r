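Package: connalign
Title: Atlas-Free Structural Connectomes and Network-Domain Alignment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Construction and connection-wise comparison of diffusion-MRI
    structural brain networks without an anatomical atlas. Cortical surfaces
    are parcellated into N equal-area nodes by recursive zonal equal-area
    partitioning of a reference sphere scaled to each individual brain;
    streamline endpoints define a dense point-to-point connectome that is
    downscaled to an N-by-N binary network. The optimal N is selected as the
    finest parcellation at which every subject's network forms a single
    connected component. Networks are compared in the network domain by
    simulated-annealing matrix alignment (node reordering minimising the
    absolute adjacency difference) with lower-triangle Pearson correlation,
    cohort reference selection, sum networks, rotation-of-parcellation
    analysis, normalised global graph metrics against degree-preserving
    random ensembles, and edge-wise two-group statistics (mass-univariate
    t-tests with false discovery rate control, and the network-based
    statistic permutation procedure). A synthetic phantom module generates
    surfaces, modular ground-truth networks and streamline sets with known
    structure so the whole pipeline is testable without MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
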