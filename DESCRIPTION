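Package: dicistro
Title: Annotation of Di-Cistronic RNA Virus Genomes and
    Composition-Based Host Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes positive-sense single-stranded RNA virus genomes
    with a di-cistronic layout (5'UTR - ORF1 - intergenic region - ORF2 -
    3'UTR): enumerates start/stop codons and open reading frames, detects the
    two-ORF architecture, scans translated polyproteins for conserved
    replicase and capsid motifs (helicase, VPg tandem repeat, protease,
    polymerase), annotates protease cleavage sites into mature peptides, and
    places PCR primers in silico. Implements nucleotide composition analysis
    (NCA): mono- and dinucleotide frequencies, observed/expected dinucleotide
    bias ratios, and a canonical (Fisher) discriminant model over host-labeled
    control sequences used to predict the host origin of an unknown virus.
    Ships a first-order Markov sequence simulator that generates host-typical
    control panels and fully specified artificial di-cistronic genomes with
    known ground-truth annotation, so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
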