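Package: orthotrace
Title: Synteny-Based Gene-Loss Detection and Cross-Lineage Promoter
    Motif Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics toolkit for establishing gene loss and
    its regulatory consequences across a species phylogeny. Calls gene
    presence/absence per species from tabular protein-to-genome alignment
    hits combined with flank-gene synteny and assembly-quality checks,
    and places loss events on a rooted species tree by Dollo parsimony.
    Scans promoter sequences with JASPAR-style position weight matrices
    under a relative profile score threshold, identifies transcription
    factor binding sites conserved within a lineage in fixed upstream
    segments, and reports elements shared across lineages anchored to a
    common proximal motif. Also provides pairwise global protein
    alignment with gap-excluded identity/similarity percentages,
    CpG-island detection, and seeded simulators that generate promoters,
    diverged ortholog sets and synthetic gene loci with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
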