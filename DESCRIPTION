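Package: diveBout
Title: Dive and Bout Analysis of Time-Depth Recorder Data with Bayesian
    Bout-Type Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing time-depth recorder (TDR) traces from
    diving marine predators. Provides zero-offset correction and dive
    detection for regularly sampled depth traces, per-dive shape metrics
    (bottom time, wiggles, skew and derived ratios), grouping of dives
    into behavioural bouts by an iterative sequential t-test on surface
    intervals, unsupervised dive- and bout-type classification
    (standardisation, principal components, k-means over a range of k,
    discriminant-function validation and parsimonious solution
    selection), and a Bayesian binomial mixed model of bout-type usage
    with factorial covariates and per-animal random effects fitted by a
    Metropolis-within-Gibbs sampler. A synthetic-data module generates
    depth traces and covariate/outcome tables with known ground truth so
    the whole pipeline can be exercised and validated without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    geosphere,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
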