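Package: torsmap
Title: Conformational Macrostates from Torsional Trajectories by
    Barrier-Weighted Density-Peaks Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies conformational macrostates of flexible organic
    molecules from dihedral-angle time series. Configurations are compared
    with a periodic distance metric in which every torsion is weighted by
    its lowest rotational free-energy barrier, so that activated
    conformational transitions dominate over fast intra-basin adjustments.
    Macrostates are found by density-peaks clustering on the resulting
    distance matrix, summarized as per-torsion probability fingerprints,
    and used to classify arbitrary (possibly biased) trajectories. For
    well-tempered metadynamics runs the package reweights conformer
    populations from the deposited bias, computes free-energy differences
    between conformers and decomposes them into potential-energy and
    entropic contributions using a solute / solute-solvent energy split.
    Includes a synthetic-trajectory generator with planted conformer
    basins for validation, and a command-line driver for the full
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
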