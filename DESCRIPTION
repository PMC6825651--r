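Package: modsar
Title: Modular Network QSAR with Optimal Piecewise Linear Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-level interpretable QSAR regression. Molecules are linked
    in a Tanimoto similarity network built from circular fingerprints at an
    optimal threshold located at the peak of the average clustering
    coefficient; network modules are detected by Louvain modularity
    optimisation; and the activity of each module is modelled by an optimal
    piecewise linear regression with L1 regularisation, selecting one
    partition descriptor, breakpoints, and a least-absolute-deviation
    linear equation per region. Trained models predict new molecules via
    explicit module-assignment rules with applicability-domain flagging,
    and the similarity network supports activity-cliff analysis. Includes
    a synthetic benchmark generator with planted module structure and
    piecewise-linear activity surfaces for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    quantreg,
    jsonlite,
    caret,
    mclust,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
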