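Package: rfmnp
Title: Whole-Cell Simulation of mRNA Translation with a Shared Ribosome Pool
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic whole-cell modelling of mRNA translation based on
    the ribosome flow model (RFM), a mean-field approximation of TASEP. Each
    gene is a chain of coarse-grained codon sites with an external initiation
    input; all chains compete for one finite pool of free ribosomes (the RFM
    network with pool, RFMNP). The package maps coding sequences and codon
    decoding times to chain rates, solves single-chain and network steady
    states, simulates periodic mRNA-level forcing and detects entrainment,
    computes amplitude statistics of translation rates, ribosome densities
    and the free pool, scores coding regions by a decoding-time measure, and
    designs synonymous fast/slow codon variants. A synthetic-genome generator
    reproduces the statistical structure of the S. cerevisiae
    parameterization so the full pipeline runs without external data.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
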