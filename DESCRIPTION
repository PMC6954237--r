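Package: burstline
Title: Timing Point Mutations in Reprogrammed Stem Cell Clones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring when point mutations arose during the clonal
    expansion of reprogrammed pluripotent stem cell lines (iPSCs, ntESCs).
    Provides a ground-truthed clonal-expansion simulator with a transient
    early hypermutation window, post-call SNV and INDEL filter chains,
    subline-based SNV discovery with perfect-phylogeny developmental-tree
    reconstruction, ultra-deep amplicon VAF estimation with group I/II
    classification and a burst-versus-continuous likelihood test, and
    96-class trinucleotide mutational-signature profiling with stage-wise
    decomposition and cosine comparison to reference signatures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
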