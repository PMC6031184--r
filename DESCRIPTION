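Package: hamtbs
Title: High-Accuracy Methylation Measurement from Targeted Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-sequencing analysis for targeted amplicon bisulfite
    sequencing (TBS) panels. Provides amplicon panel handling (BED + FASTA),
    cytosine context enumeration and in-silico bisulfite conversion,
    a bisulfite amplicon read simulator with truth tables, overlap trimming
    of paired-end reads, per-site methylation calling in CpG and CHH context
    with read-evidenced CpG discovery, the three quality-control filters of
    the HAM-TBS protocol (bisulfite conversion rate, PCR-artifact removal,
    minimum coverage), titration-based assay validation statistics
    (per-CpG linearity, condition comparison, replicate SD), and the
    coverage-accuracy subsampling bootstrap used to choose a minimum
    coverage cutoff.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
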