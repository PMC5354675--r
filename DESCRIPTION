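Package: melafidelity
Title: Quantifying How Well Melanoma Cell Lines Recapitulate Tumours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the fidelity of melanoma cell lines as tumour
    models. Implements tumour-purity-aware differential expression between cell
    lines and tumours with partitioning of top genes by immune/stromal score
    correlation, an immune gene signature score with Kaplan-Meier/log-rank
    survival analysis, ranking of cell lines by mean Pearson correlation to
    single malignant cells (overall and within MITF-high/AXL-high cell
    subsets), control-matched MITF/AXL program scoring and kernel-density
    state clustering, UV mutational-signature classification from
    trinucleotide-context SNV catalogs, tissue-of-origin skin scoring with
    squared-enrichment gene weights, copy-number event calling, and a per-line
    genomic summary table. A seeded synthetic-cohort generator emulating
    purity-admixed tumours, pure cell lines, two-state single cells, UV
    mutation catalogs and immune-linked survival makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
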