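Package: sweepOverlap
Title: Cross-Species Overlap Analysis of Selective-Sweep Candidate Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether candidate-gene lists from
    selective-sweep screens in different species overlap more than
    expected by chance. Harmonizes heterogeneous published gene lists
    (symbol normalization, alias resolution, non-coding filtering),
    computes pairwise and multi-set overlaps with Venn decomposition,
    evaluates overlap significance with the exact hypergeometric
    intersection distribution and a seeded Monte Carlo null, validates
    that shared symbols are orthologs by flanking-gene synteny
    conservation, and runs configurable batteries of comparisons with
    reproducible reports. Includes a synthetic-data generator (gene
    pools with planted overlap, alias and non-coding noise, rearranged
    gene neighborhoods) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
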