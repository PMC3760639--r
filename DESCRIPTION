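Package: exocargo
Title: Profiling the mRNA and microRNA Cargo of Exosomes from Paired Array Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipelines for characterizing the RNA cargo of exosomes
    relative to their donor cells from microarray data. Implements the
    two-channel (Hy3/Hy5) microRNA workflow -- slide-level background
    estimation, replicate-based detection calls, cross-slide reliability
    aggregation, global lowess (MA) ratio normalization, triplicate
    log2-ratio summaries and fold-change classification, and Venn set
    algebra over detected compartments -- and the single-channel mRNA
    workflow: median scaling to a target array intensity, group-wise
    top-quantile intensity filtering, Present/Marginal/Absent call
    filtering and compartment-unique set construction. A synthetic-data
    generator with known compartment structure and injected dye bias makes
    every stage testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
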