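Package: gemscreen
Title: Genome-Scale Metabolic Modeling for Tumor Drug-Target Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constraint-based analysis of genome-scale metabolic models
    (GEMs) aimed at drug-target discovery in tumors, with glioblastoma as
    the motivating application. Provides flux balance analysis on an
    internal bounded-variable simplex, boolean gene-protein-reaction rule
    evaluation and logic transformation for fast single-gene knockout
    scans, ensemble model comparison (reaction-presence Hamming distances,
    hierarchical top-split clustering) and merging into a generic model,
    metabolic-task feasibility checking on healthy-tissue models to screen
    knockout toxicity, reporter-metabolite and reporter-subnetwork scoring
    of differential expression over model topology, Pearson co-expression
    networks with random-walk community detection, survival stratification
    and CRISPR dependency-score validation statistics, and synthetic-data
    generators with planted ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
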