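Package: connscreen
Title: Connectivity-Map Signature-Reversal Screening and Drug-Combination
    Synergy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for in-silico drug repurposing against transcriptional
    signatures and for quantifying drug-combination synergy. Expression
    profile collections (GCT text format) are converted to per-gene robust
    z-scores, scored against up/down query gene signatures with the
    Kolmogorov-Smirnov connectivity statistic, and screened at the drug
    level by pre-ranked enrichment analysis with permutation-based
    normalized enrichment scores and p-values. Drug-combination viability
    data are analysed with the Chou-Talalay median-effect model: per-drug
    (m, Dm) fits, combination indices for non-fixed-ratio dose pairs, and
    Fa-CI summaries. Synthetic-data generators with known ground truth
    (planted signature-reversing drugs, known median-effect parameters and
    interaction strength) make every stage testable without proprietary
    profile collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    fgsea,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
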