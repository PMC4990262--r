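Package: consensusSort
Title: Consensus-Based Spike Sorting by Evidence Accumulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spike sorting for multichannel extracellular recordings based on
    consensus clustering by evidence accumulation. An ensemble of K-means-seeded
    template-matching partitions is combined into pairwise co-assignment
    probabilities; core clusters are extracted with an inconsistency-coefficient
    cut and merged by single-link agglomeration on misclassification-rate
    distances; overlapping spikes are resolved by matching pursuit over final
    templates; and each unit's false-positive and false-negative rates are
    estimated from the stability of its spikes across the clustering ensemble.
    Includes a synthetic-recording generator with ground truth, ground-truth
    scoring, and per-unit quality metrics (SNR, refractory violations,
    isolation distance).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    nortest,
    MASS,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
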