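Package: binpolish
Title: Differential-Coverage Refinement of Metagenome-Assembled Genome Bins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Purifies preliminary metagenome bins using two-sample
    differential coverage: median-outlier removal, splitting of sub-bins with
    inverse relative coverage profiles, and iterative z-score based
    decontamination with a shrinking cutoff. Adds lowest-common-ancestor
    (LCA) taxonomic filtering of scaffolds assigned to foreign phyla, strict
    end-to-end read recruitment for targeted reassembly, post-hoc linking of
    16S rRNA scaffolds to bins by coverage profile, depth-weighted relative
    abundance and tRNA-isotype completeness estimators, and selection of the
    single-copy unique core genome from ortholog tables. A synthetic
    community generator with planted contaminants makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
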