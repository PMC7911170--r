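Package: motifclust
Title: K-Mer Motif Profiling, Markov D-Ratio Representation, and
    Composition-Based Clustering of Viral Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles multi-record DNA FASTA inputs by overlapping k-mer
    motif frequencies (k = 1..5), scores motif over- and
    under-representation with a maximal-order Markov model D-ratio
    (observed over expected frequency), assembles per-sequence profiles
    into feature matrices with max-absolute normalization, and clusters
    sequences by K-means, PCA plus K-means, mean shift, and hierarchical
    clustermap ordering. Includes bar-chart, heatmap, clustered-heatmap
    and PCA-scatter rendering, a synthetic-sequence generator with
    controlled base composition and Markov structure for testing, and a
    command-line interface covering the full pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    grDevices,
    graphics,
    grid,
    rlang,
    jsonlite,
    optparse,
    pheatmap,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
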