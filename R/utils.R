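#' @keywords internal
"_PACKAGE"

# Lower-median: for even-length vectors take the lower of the two middle
# order statistics. Deterministic tie convention used for all median-matching
# rescaling in the package (initiation rates, decoding rates).
median_low <- function(x) {
  n <- length(x)
  stopifnot(n >= 1L)
  sort(x)[ceiling(n / 2)]
}

# Sense codons and synonymous groups from the standard genetic code.
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

synonymous_groups <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
}

# amino acid of each sense codon, named character vector
codon_to_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc[gc != "*"]
}

stop_codons <- c("TAA", "TAG", "TGA")
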