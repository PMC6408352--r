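Package: recticluster
Title: Constrained Tensor Clustering and Mechanistic Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters multi-indexed (tensor-valued) experimental data under
    algebraic rectangularity constraints that keep clusters mechanistically
    interpretable. Similarity tensors are built from flattened data tensors;
    optimal rectangular partitions of an experiment grid are found by exact
    integer programming, either directly from the similarity tensor or by
    refining a pre-existing clustering to its nearest rectangular partition.
    A downstream stage systematically enumerates, simulates, fits and ranks
    (by small-sample corrected AIC) three-species receptor/pERK/pAKT
    crosstalk ODE models for each cluster. Includes a synthetic data
    generator with planted rectangular cluster structure so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
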