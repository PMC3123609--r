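Package: CoevolMI
Title: Background-Corrected Mutual Information Measures of Residue
    Coevolution in Protein Alignments
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the covariation of column pairs in protein multiple
    sequence alignments with four mutual-information measures: classical MI
    normalized by the joint entropy (MI'), MI with marginals corrected by the
    BLOSUM62 amino-acid background distribution (MIB'), MI over Taylor's ten
    overlapping physicochemical property groups (MIP'), and the
    property-level measure with the property background removed (MIBP').
    Includes the alignment preprocessing the measures assume (identity-based
    redundancy removal, gap-column filtering, depth checks), the conn(k)
    per-site covariation connectivity indicator, a synthetic-alignment
    simulator with controlled coevolution structure, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Alignment, SequenceMatching, Proteomics, Software
RoxygenNote: 7.3.3
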