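Package: oligoband
Title: Oligo-Banding Karyotype Design and Rearrangement Calling
Version: 0.1.0
Authors@R:
    person("Oligoband", "Developers", email = "oligoband@example.org",
           role = c("aut", "cre"))
Description: Toolkit for fluorescent oligo-banding karyotyping: design of
    oligonucleotide FISH probe panels from candidate 39mer coordinates under
    density, coverage, spacing and chromosome-termini rules; selection of a
    six-colour banding scheme maximizing between-chromosome Levenshtein
    distance; assembly of synthesis-ready oligos with orthogonal primer and
    detection-handle sequences screened by nearest-neighbor dimerization free
    energy; extraction of multi-channel intensity profiles along traced
    chromosomes, band calling, signature matching and calling of chromosomal
    rearrangements (reciprocal translocations, insertions, non-reciprocal
    translocations) with genomic breakpoint intervals; a 2:2 meiotic
    segregation model for sperm-FISH signal classification; and a synthetic
    data generator producing candidate tables, band profiles, spread images
    and sperm-head signal fields with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
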