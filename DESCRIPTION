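Package: mirkey
Title: Network-Based Prioritization of Key Disease miRNAs from
    Drug-Reversal Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Identifies key disease microRNAs by combining four-group
    (control, disease, disease+drug, drug-only) expression profiles with
    weighted protein-protein interaction networks.  Classifies
    drug-reversed dysregulated miRNAs, scores each miRNA's regulatory
    capacity from target-node degree and neighborhood connectivity
    (static score), measures regulatory efficiency by perturbing target
    protein concentrations in a mass-action binding equilibrium model
    (dynamic score), and locates each candidate's regulatory emphasis via
    cohesiveness-based overlapping module discovery with hypergeometric
    gene-set enrichment.  Includes a synthetic-data generator with
    planted ground truth so every stage of the pipeline is verifiable.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
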