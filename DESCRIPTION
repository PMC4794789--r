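Package: gentscan
Title: Group-Specific Conservation Analysis of Protein Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative conservation analysis of protein multiple sequence
    alignments partitioned into subfamilies (groups). Provides per-column
    conservation profiling with the 100%/80-99%/60-79% banding convention,
    reference-residue to alignment-index mapping, a group-entropy versus
    family-entropy scan for group-specific conserved positions,
    conserved-motif discovery with bracket-notation consensus patterns,
    a distance-based phylogeny stage (gap trimming, p/Kimura protein
    distances, neighbor joining, bootstrap, majority-rule consensus,
    per-group clade support), a synthetic alignment generator with planted
    column archetypes for validation, and a one-command pipeline writer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    seqinr,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
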