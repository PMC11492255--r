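Package: zwscan
Title: Coverage-Ratio Detection of ZW Sex-Chromosome Regions and Hox
    Cluster Organization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects ZW sex-chromosome structure from female and male
    whole-genome sequencing depth. Windowed read depths are normalized per
    sex and classified by the log2 male:female ratio into pseudoautosomal,
    female-specific (W), Z-specific and undetermined regions; contiguous
    regions are segmented, W-derived contigs are identified through an AGP
    scaffold description and extracted from the Z chromosome, and candidate
    sex-determining genes are prioritized by sex-biased expression within
    the called regions. A second component reconstructs Hox cluster
    organization from a gene annotation, partitions the cluster into
    gap-separated subclusters and compares gene order and transcriptional
    orientation across species to locate putative inversion sites. A seeded
    synthetic-data generator emulates a diploid assembly with a ZW-mixed
    chromosome so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
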