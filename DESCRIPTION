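Package: CytoMembership
Title: GMM-Based Expanded Feature Space for Mass Cytometry Clustering
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes each mass-cytometry marker's intensity distribution
    into a univariate Gaussian mixture (EM with BIC model selection under a
    minimal-sigma constraint), converts component posteriors into corrected
    single-peaked membership functions, and projects cells into the expanded
    membership feature space so that downstream clustering separates cell
    subpopulations - including rare ones - better than in the raw marker
    space. Includes artifact detection and correction for posterior curves,
    internal clustering validity indices (Calinski-Harabasz, Davies-Bouldin),
    a labeled synthetic-cytometry generator, FCS and delimited-text input,
    and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    withr,
    jsonlite,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
biocViews: SingleCell, FlowCytometry, Proteomics, Clustering, FeatureExtraction
RoxygenNote: 7.3.3
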