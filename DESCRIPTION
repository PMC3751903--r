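Package: chimdetect
Title: Detection of Chimeric Transcripts from De Novo Assembly Contigs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and characterizes chimeric transcripts (gene fusions,
    partial tandem duplications, and internal tandem duplications) from
    contig-to-genome alignments of de novo transcriptome assemblies.
    Implements alignment-set selection over split and gapped contig
    alignments, breakpoint read-support estimation from read-to-contig
    alignments, a ten-filter candidate screen, event typing against gene
    models, and estimation of chimeric versus wild-type relative coverage
    from read-to-genome alignments. Ships a synthetic genome/event/read
    generator and an ideal-alignment synthesizer so the whole pipeline can
    be exercised without an external aligner or assembler.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rsamtools,
    IRanges,
    GenomicRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
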