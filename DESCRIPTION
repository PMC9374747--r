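Package: transomix
Title: Construction of Glucose-Responsive Regulatory Trans-Omic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds regulatory trans-omic networks for glucose-responsive
    metabolism from two-genotype (wild-type versus ob/ob) multi-omic time
    courses. Implements responsiveness calling with Welch tests, Storey
    q-values, fold-change thresholds and T1/2 response-speed classes;
    dendrogram-guided transcription-factor inference via one-tailed Fisher
    motif enrichment with a child-cluster exclusion rule; assembly of a
    five-layer (insulin signal, transcription factor, enzyme, reaction,
    metabolite) network with signed, genotype-attributed interlayer edges;
    and pathway-level condensation of the reaction layer. A synthetic-data
    module generates multi-omic time courses and knowledge tables with
    planted ground truth so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
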