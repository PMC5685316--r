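Package: gaknn
Title: Biomarker Panel Discovery with Genetic Algorithm k-Nearest Neighbours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and evaluation of small diagnostic gene-expression
    panels from two-class cohorts, modelled on the GA/kNN strategy used in
    peripheral-blood stroke transcriptomics. Provides fold-change filtering
    and per-gene z-transformation, a genetic-algorithm search that pools
    near-optimal gene combinations scored by leave-one-out k-nearest-neighbour
    classification and ranks genes by selection frequency, leave-one-out
    panel metrics with random-panel benchmarking, principal-component
    composite expression scores, Lindeman-Merenda-Gold (LMG) relative
    importance decomposition for confounder analysis, cohort summary
    statistics (Welch t, Pearson chi-square, Spearman rho, Holm adjustment),
    and a synthetic cohort generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    class,
    jsonlite
Config/testthat/edition: 3
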