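Package: connremod
Title: Longitudinal Structural Connectome Remodeling Analysis
Version: 0.1.0
Authors@R:
    person("Connremod", "Developers", email = "connremod@example.org",
           role = c("aut", "cre"))
Description: Construction and longitudinal analysis of COMMIT-weighted
    structural brain connectomes under surgical resection masks. Provides a
    synthetic cohort generator (lateralized parcellations on voxel label
    volumes, streamline records with signal contributions, planted
    multiplicative connectivity effects), subject-wise timepoint-invariant
    parcellation masking, connection-weight matrix assembly with
    side-flipping and group prevalence thresholding, weighted graph-theory
    metrics (betweenness centrality, Onnela clustering, local and global
    efficiency, characteristic path length, small-worldness), and
    subject-level sign-flip permutation paired t-tests with
    Benjamini-Hochberg false discovery control, interval comparison of
    absolute connectivity changes, and lateralization chi-square analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
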