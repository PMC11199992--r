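Package: toxconcord
Title: Transcriptomic Concordance Analysis for Chemical Mode-of-Action Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A tested pipeline for comparing the transcriptomic response of a
    test chemical against mechanistic positive controls in primary hepatocyte
    concentration-response studies. Covers sample-level sequencing QC and
    cytotoxicity calls, probe-level differential expression on targeted
    (TempO-Seq-style) count matrices with median-of-ratios normalization,
    direction-specific hypergeometric gene-set overrepresentation, binarized
    activity-concurrence matrices and Jaccard concordance between chemicals,
    interacting-gene (ToxPi-style) score aggregation, and simplified benchmark
    concentration (BMC) modeling with a Williams trend permutation prefilter.
    A seeded negative-binomial study simulator with planted pathway effects
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, Rcpp, minpack.lm
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
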