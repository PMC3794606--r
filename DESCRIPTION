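Package: p53REcode
Title: Response-Element Transactivation Code for p53-Family Transcription
    Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the sequence-level analysis of p53/p63/p73 response
    elements (REs). Scans DNA for canonical and non-canonical (half- and
    three-quarter) sites matching the degenerate RRRCWWGYYY-(n)-RRRCWWGYYY
    consensus, computes the RY (GG/CC flanking dinucleotide) signature and
    CWWG-core WW motifs that predict altered transactivation by
    change-of-spectrum DNA-binding-domain mutants such as p73 S139F,
    classifies per-RE transactivation changes between alleles and tests
    signature-class association with Fisher's exact test, summarises RE sets
    as paired-dinucleotide sequence logos, and fits cooperative Hill binding
    curves (EC50 as Kd, Hill coefficient, censoring for unsaturated
    titrations) to fluorescence-polarization data. A seeded synthetic-data
    generator emulates RE sets, yeast luciferase transactivation measurements
    and 18-point titration curves so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils-iupac.R'
    'AllGenerics.R'
    'AllClasses.R'
    'cli.R'
    'hill.R'
    'io.R'
    'logo.R'
    'p53REcode-package.R'
    'scan.R'
    'signature.R'
    'synthetic.R'
    'transactivation.R'
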