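Package: hsforest
Title: Partial Clustering of Protein Decoy Sets for Correct-Fold Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Selects the best candidate structure (decoy) from large ab
    initio protein structure prediction decoy sets without clustering
    every decoy.  Random pivot decoys define median-split hashing
    functions over the C-alpha RMSD (or GDT-TS) metric space; randomized
    binary hash trees detect dense "cluster nodes" balanced in height and
    size; cluster representatives are ranked by their total distance to
    the lowest-energy decoys and a consensus over many trees is returned.
    Includes the evaluation criteria used for correct-fold detection
    benchmarks and a synthetic decoy-set generator with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
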