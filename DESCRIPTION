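Package: indexsel
Title: Optimal Selection of Sequencing Barcode Subsets by Integer Programming
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects a subset of sample-index (barcode) sequences from a larger
    candidate pool for multiplexed high-throughput sequencing. The selection is
    cast as a mixed-integer linear program that minimizes a nucleotide-balance
    cost (per-position balance of the Illumina two-laser groups A/C and G/T,
    per-position balance of the four single nucleotides, and global nucleotide
    balance) subject to a minimum pairwise sequence-distance constraint
    (Hamming or Levenshtein) and a fixed subset size. Supports selecting a new
    set, checking the compatibility of an existing set, and augmenting an
    already-committed set with additional compatible barcodes. Includes a
    synthetic candidate-pool generator with planted optimal subsets for
    testing, balance diagnostics as tables and plots, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
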