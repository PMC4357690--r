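Package: raavarms
Title: Design of Homology Arms and Targeting Scenarios for rAAV Genome Editing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs recombinant adeno-associated virus (rAAV) gene-targeting
    constructs for human protein-coding genes. Parses CCDS-style annotation
    tables into exon, unique-exon and exon-projection databases, extracts
    soft-masked genomic target regions with 3 kb flanks, enumerates candidate
    homology arms (700-1200 bp PCR products) with a sliding-window primer
    design engine and repeat/mononucleotide filters, clusters arms with
    DBSCAN, and generates, scores and ranks knock-in (left-span / span-right)
    and knock-out (partial deletion / whole-exon excision) scenarios, capped
    at five per category per exon. Includes Gateway attB primer tailing,
    TSV/JSON/BED export, coverage-optimization statistics for tuning the
    sliding-window parameters, and a deterministic synthetic genome and
    annotation simulator with ground truth for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
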