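Package: duplexmip
Title: Design and Analysis of Duplex Molecular Inversion Probe Capture Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Designs duplex molecular inversion probe (MIP) panels over tiled,
    overlapping target regions: annealing-arm candidates are enumerated at five
    lengths and five shifts, screened for restriction sites, genomic redundancy,
    homopolymers and extreme GC, and scored by nearest-neighbor melting
    temperature; surviving probes are assembled into microarray-ready duplex
    precursor oligonucleotides with 10-nt unique barcodes, EarI release
    cassettes, spacers and amplification primer regions. A companion read
    processor identifies probe arms in paired-end capture reads, extracts
    barcodes and gap-fill sequences, removes PCR duplicates by (probe, barcode)
    key, and computes capture accounting, uniformity and saturation statistics.
    A capture simulator generates reference sequences, variants, capture events
    with PCR duplication and paired FASTQ reads with a truth table, so the full
    stack is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
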