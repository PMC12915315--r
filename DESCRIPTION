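Package: tigdesign
Title: Design and Comparative Analysis Toolkit for Endogenous Type I-G CRISPR-Cas Genome Editing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs genome-editing reagents for bacteria that carry an
    endogenous Type I-G CRISPR-Cas system: scans target genes for the
    5'-TAT-3' PAM, extracts 35 nt protospacers on either strand, screens
    candidate spacers genome-wide for off-targets under the PAM-proximal
    seed rule (positions 1-8), plans knockout deletion windows, builds
    homology-arm editing templates, assembles synthetic CRISPR cassettes
    (leader, two consensus repeats flanking the spacer, terminator) and
    complete screening/editing vectors in silico, and designs verification
    primers outside the homology arms. Also provides comparative CRISPR
    locus analytics on small or synthetic genome sets: de novo array
    detection, repeat consensus, cross-genome spacer catalogs, array
    diffing by longest common subsequence, self-targeting scans, and
    exact-identity protein clustering. A deterministic synthetic-genome
    generator with planted ground truth makes every step testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
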