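Package: satselseq
Title: Saturation Mutagenesis, Selection and Sequencing (Sat-Sel-Seq) Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, simulation and analysis tools for Sat-Sel-Seq experiments:
    saturation mutagenesis libraries built from a degenerate NNS codon with an
    adjacent silent-codon positional barcode, iterated functional selection, and
    amplicon sequencing with generational barcodes.  The package designs
    positional and covariation libraries, simulates fitness-weighted selection
    campaigns with realistic sequencing noise, decodes reads by dual barcodes,
    tabulates codon counts and generational enrichment with starting-library
    correction, and quantifies downstream assays (substrate-context preference
    profiles, fluctuation mutation frequencies, Michaelis-Menten kinetics) and
    structural trajectory geometry (residue-to-DNA contacts, hydrogen-bond
    occupancy, solvent-accessible surface area).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    bio3d,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
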