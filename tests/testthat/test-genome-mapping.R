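test_that("ORF partition reproduces the worked examples", {
  p <- partition_orf(146)
  expect_equal(p$n, 14)
  expect_equal(p$piece_sizes, c(9L, rep(10L, 13), 7L))
  p2 <- partition_orf(239)
  expect_equal(p2$n, 23)
  expect_equal(p2$piece_sizes, c(9L, rep(10L, 22), 10L))
  p3 <- partition_orf(25)
  expect_equal(p3$piece_sizes, c(9L, 10L, 6L))
  expect_equal(p3$n, 2)
})

test_that("partition invariants hold for every ORF length in range", {
  bad <- Filter(function(K) {
    p <- partition_orf(K)
    s <- p$piece_sizes
    last <- s[length(s)]
    !(sum(s) == K && s[1] == 9L &&
        (p$n <= 1 || all(s[2:p$n] == 10L)) &&
        last >= 5 && last <= 15)
  }, 25:4911)
  expect_length(bad, 0)
})

test_that("too-short ORFs are rejected", {
  expect_error(partition_orf(13), "too small")
  expect_silent(partition_orf(14))
})

test_that("chain rates follow the reciprocal-sum formulas", {
  tab <- uniform_table()          # all tau = 0.15625
  orf <- rep("GCT", 146)
  g <- gene_record("g", orf, 1, 0.8)
  spec <- rates_from_orf(g, tab)
  expect_equal(spec$n, 14)
  # interior pieces of 10 codons: lambda = 1/(10 * 0.15625) = 0.64
  expect_close(spec$lambda[2:14], 0.64, 1e-12)
  # last piece: 7 codons
  expect_close(spec$lambda[15], 1 / (7 * 0.15625), 1e-12)
  # lambda0 = 1/(1/p + 9 * tau) = 1/(1.25 + 1.40625)
  expect_close(spec$lambda[1], 1 / (1.25 + 1.40625), 1e-12)
  expect_equal(spec$copy_weight, 1)
  # p -> Inf limit: lambda0 -> 1/S with S the first-piece time
  g2 <- gene_record("g", orf, 1, 1e12)
  expect_close(rates_from_orf(g2, tab)$lambda[1], 1 / 1.40625, 1e-9)
})

test_that("rates are invariant to synonymous substitutions with equal tau", {
  tab <- generate_codon_table(seed = 2, spread = 0.4)
  # force two synonyms of Ala to share tau, then swap them in the ORF
  tab$tau["GCT"] <- tab$tau["GCC"]
  orf1 <- rep(c("GCT", "CGT"), 20)
  orf2 <- rep(c("GCC", "CGT"), 20)
  s1 <- rates_from_orf(gene_record("a", orf1, 1, 0.8), tab)
  s2 <- rates_from_orf(gene_record("b", orf2, 1, 0.8), tab)
  expect_equal(s1$lambda, s2$lambda)
})

test_that("decoding-time normalization hits the per-gene median and is idempotent", {
  sys <- tiny_system(7, seed = 31)
  tab <- sys$table
  rate_g <- vapply(sys$genome$genes,
                   function(g) length(g$orf) / sum(tab$tau[g$orf]), 0)
  expect_close(sort(rate_g)[ceiling(7 / 2)], 6.4, 1e-10)
  tab2 <- normalize_decoding_times(tab, sys$genome)
  expect_close(tab2$tau / tab$tau, 1, 1e-12)  # second pass is the identity
  # uniform-tau table: every gene ends at exactly 6.4 codons/s
  u <- normalize_decoding_times(uniform_table(3.2), sys$genome)
  rate_u <- vapply(sys$genome$genes,
                   function(g) length(g$orf) / sum(u$tau[g$orf]), 0)
  expect_close(rate_u, 6.4, 1e-10)
})

test_that("3-gene brute-force median check of the normalization scale", {
  tab <- generate_codon_table(seed = 5, spread = 0.6)
  genes <- lapply(1:3, function(i)
    gene_record(paste0("g", i), toy_orf(25 + 5 * i, seed = i), 1, 0.8))
  genome <- structure(list(genes = genes, total_mrna = 3,
                           total_ribosomes = 10), class = "genome")
  rates <- vapply(genes, function(g) length(g$orf) / sum(tab$tau[g$orf]), 0)
  s_manual <- sort(rates)[2] / 6.4
  tab2 <- normalize_decoding_times(tab, genome)
  expect_close(tab2$tau, tab$tau * s_manual, 1e-12)
})

test_that("initiation estimation scales density/mRNA to the target median", {
  expect_equal(estimate_initiation(c(2, 4, 8), c(1, 1, 1)), c(0.4, 0.8, 1.6))
  expect_equal(estimate_initiation(rep(3, 5), rep(2, 5)), rep(0.8, 5))
  # permutation equivariance
  set.seed(3)
  d <- stats::runif(9, 1, 5); m <- stats::runif(9, 1, 5)
  perm <- sample(9)
  expect_equal(estimate_initiation(d, m)[perm],
               estimate_initiation(d[perm], m[perm]))
  expect_error(estimate_initiation(c(1, 2), c(1, 0)), "mRNA")
})
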