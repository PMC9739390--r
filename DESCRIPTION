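Package: tfchronet
Title: Temporal Transcription-Factor Network Inference from Time-Course
    Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing daily bulk transcriptomes along a directed
    differentiation time course and inferring the directed, signed, lagged
    regulatory network among transcription factors.  Genes are ranked by a
    moderated multivariate Hotelling-type time-course statistic, grouped
    into chronologically ordered temporal expression waves by k-means, and
    scored pairwise with a maximum-absolute-correlation (MAC) statistic over
    bounded time lags with a permutation null.  The inferred network can be
    compared quantitatively against an undirected weighted reference
    protein-protein-interaction network, and seed-TF downstream sub-networks
    extracted.  A synthetic-data module generates time courses with known
    wave structure and known lagged signed regulation for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    jsonlite,
    yaml,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
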