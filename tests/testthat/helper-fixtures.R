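# Small systems shared across tests; everything is generated in code.

# tiny genome + normalized table + chain specs (cached per-session)
tiny_system <- local({
  cache <- new.env(parent = emptyenv())
  function(n_genes = 8, seed = 42, length_range = c(25L, 400L)) {
    key <- paste(n_genes, seed, paste(length_range, collapse = "-"))
    if (is.null(cache[[key]])) {
      genome <- generate_genome(n_genes, seed = seed,
                                length_range = length_range,
                                total_mrna = 60000 * n_genes / 6310,
                                total_ribosomes = 200000 * n_genes / 6310)
      table <- normalize_decoding_times(
        generate_codon_table(seed = seed + 1, spread = 0.5), genome)
      cache[[key]] <- list(
        genome = genome, table = table,
        specs = lapply(genome$genes, rates_from_orf, table = table),
        H0 = genome$total_ribosomes, L_T = genome$total_mrna)
    }
    cache[[key]]
  }
})

# uniform-tau table (all codons decode at the same rate)
uniform_table <- function(rate = 6.4) {
  tab <- generate_codon_table(seed = 1, spread = 0, target_rate = rate)
  stopifnot(all(abs(tab$tau - 1 / rate) < 1e-15))
  tab
}

# a toy protein of K codons drawn from groups with several synonyms
toy_orf <- function(K, seed = 7) {
  set.seed(seed)
  sample(c("GCT", "CGT", "CTA", "TCG", "GGA", "ACC"), K, replace = TRUE)
}

expect_close <- function(actual, expected, tol = 1e-8) {
  expect_lt(max(abs(actual - expected)), tol)
}
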