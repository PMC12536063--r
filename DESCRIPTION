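Package: IGHclonal
Title: Clonality and Mutational Status of IGH Rearrangements from
    Short-Read Amplicon Sequencing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs clonal immunoglobulin heavy-chain (IGH) VDJ
    rearrangements from paired-end 2x150 bp framework-region (FR1/FR2/FR3,
    optionally leader) amplicon reads. Reads are quality-trimmed, assigned
    to germline IGHV/IGHJ alleles by local alignment, linked into V-J
    pairings, and collapsed into a per-rearrangement consensus sequence
    built against a concatenated V-J germline reference. Each consensus is
    annotated with germline V identity (somatic hypermutation load),
    mutational status (unmutated/borderline/mutated), CDR3 via the
    conserved Cys104/Trp118/WGxG motifs, and an inferred IGHD segment.
    Mapping artifacts are merged by consensus identity and fragment
    support, and repertoire structure (polyclonal versus N-clone, with a
    per-sample clonal/subclonal cut-off) is determined from the MAX_DIFF
    consecutive-abundance-ratio statistic and a k-nearest-neighbour
    classifier. A synthetic-repertoire simulator generates ground-truth
    rearrangements, abundance profiles, and paired FASTQ reads for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    class,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Sequencing, ImmunoOncology, SomaticMutation, Classification
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'IGHclonal-package.R'
    'annotation.R'
    'artifactFilter.R'
    'assign.R'
    'clonality.R'
    'germlineDb.R'
    'pipeline.R'
    'readPrep.R'
    'rearrangements.R'
    'utils.R'
    'synthetic.R'
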