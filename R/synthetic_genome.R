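#' Generate a synthetic codon decoding-time table
#'
#' Draws one decoding time (seconds per codon) for each of the 61 sense
#' codons, i.i.d. log-normal on the log scale, then rescales all times by one
#' multiplicative constant so that the median per-codon decoding rate
#' \eqn{1/\tau} equals \code{target_rate} codons per second (6.4 by default,
#' the calibration used for the whole-cell parameterization). Synonymous
#' groups follow the standard genetic code; stop codons are excluded
#' throughout the package.
#'
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param spread log-scale standard deviation of the log-normal draw;
#'   \code{spread = 0} gives identical times \code{1/target_rate} for all
#'   codons.
#' @param target_rate median per-codon decoding rate after rescaling, in
#'   codons per second.
#' @return an object of class \code{codon_table}: a list with \code{tau}
#'   (named numeric, 61 sense codons) and \code{groups} (list of synonymous
#'   codons per amino acid).
#' @examples
#' tab <- generate_codon_table(seed = 1, spread = 0.5)
#' stats::median(1 / tab$tau)  # 6.4
#' @export
generate_codon_table <- function(seed, spread = 0.5, target_rate = 6.4) {
  stopifnot(spread >= 0, target_rate > 0)
  codons <- sense_codons()
  set.seed(as.integer(seed))
  tau <- exp(stats::rnorm(length(codons), mean = log(1 / target_rate), sd = spread))
  names(tau) <- codons
  # one multiplicative rescale: median decoding rate 1/tau -> target
  s <- stats::median(1 / tau) / target_rate
  tau <- tau * s
  structure(list(tau = tau, groups = synonymous_groups()),
            class = "codon_table")
}

#' @export
print.codon_table <- function(x, ...) {
  cat("codon decoding-time table: ", length(x$tau), " sense codons, ",
      length(x$groups), " synonymous groups\n", sep = "")
  cat(sprintf("  tau range [%.4g, %.4g] s, median decoding rate %.4g codons/s\n",
              min(x$tau), max(x$tau), stats::median(1 / x$tau)))
  invisible(x)
}

validate_codon_table <- function(table) {
  stopifnot(inherits(table, "codon_table"),
            length(table$tau) == 61L,
            all(is.finite(table$tau)), all(table$tau > 0),
            setequal(names(table$tau), unlist(table$groups)))
  invisible(table)
}

#' Construct a gene record
#'
#' @param gene_id character identifier.
#' @param orf character vector of codons (stop codon excluded), length
#'   \eqn{K \ge 25}.
#' @param mrna_level mRNA copy number (nonnegative real; 0 allowed for a
#'   reporter whose level is set later by an experiment).
#' @param initiation_rate initiation rate \eqn{p} in events per second.
#' @return an object of class \code{gene_record}.
#' @export
gene_record <- function(gene_id, orf, mrna_level, initiation_rate) {
  stopifnot(is.character(orf), length(orf) >= 25L,
            !any(orf %in% stop_codons),
            all(orf %in% sense_codons()),
            mrna_level >= 0, initiation_rate > 0)
  structure(list(gene_id = as.character(gene_id), orf = orf,
                 mrna_level = mrna_level, initiation_rate = initiation_rate),
            class = "gene_record")
}

#' Generate a synthetic genome
#'
#' Emulates the statistical structure of the whole-cell parameterization:
#' ORF lengths log-uniform over \code{length_range} (heavy right tail),
#' codons uniform over the 61 sense codons, mRNA copy numbers log-normal
#' (spanning orders of magnitude) rescaled to sum exactly to
#' \code{total_mrna}, and initiation rates log-normal rescaled so their
#' median equals \code{median_initiation} (lower-median convention for even
#' gene counts).
#'
#' @param n_genes number of genes (\eqn{\ge 2}).
#' @param seed integer seed.
#' @param length_range integer pair within \code{[25, 4911]}, ORF length in
#'   codons.
#' @param total_mrna total mRNA copy number in the cell (default 60000).
#' @param total_ribosomes total ribosome count \eqn{H_0} (default 200000).
#' @param mrna_sdlog log-scale sd of the mRNA-level draw (default 1.5).
#' @param median_initiation target median initiation rate in /s (default 0.8).
#' @param init_sdlog log-scale sd of the initiation-rate draw.
#' @return an object of class \code{genome}: list with \code{genes} (list of
#'   \code{gene_record}), \code{total_mrna}, \code{total_ribosomes}.
#' @export
generate_genome <- function(n_genes, seed, length_range = c(25L, 4911L),
                            total_mrna = 60000, total_ribosomes = 200000,
                            mrna_sdlog = 1.5, median_initiation = 0.8,
                            init_sdlog = 0.5) {
  stopifnot(n_genes >= 2, length(length_range) == 2,
            total_mrna > 0, total_ribosomes > 0)
  if (length_range[1] < 25 || length_range[2] > 4911 ||
      length_range[1] > length_range[2])
    stop("length_range must lie within [25, 4911]")
  set.seed(as.integer(seed))
  codons <- sense_codons()
  lens <- round(exp(stats::runif(n_genes, log(length_range[1]),
                                 log(length_range[2]))))
  lens <- pmin(pmax(lens, length_range[1]), length_range[2])
  mrna <- exp(stats::rnorm(n_genes, sd = mrna_sdlog))
  mrna <- mrna * (total_mrna / sum(mrna))
  p <- exp(stats::rnorm(n_genes, sd = init_sdlog))
  p <- p * (median_initiation / median_low(p))
  genes <- lapply(seq_len(n_genes), function(i) {
    gene_record(sprintf("g%04d", i),
                sample(codons, lens[i], replace = TRUE),
                mrna[i], p[i])
  })
  structure(list(genes = genes, total_mrna = total_mrna,
                 total_ribosomes = total_ribosomes),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  K <- vapply(x$genes, function(g) length(g$orf), 0L)
  cat(sprintf("genome: %d genes, ORF lengths %d-%d codons\n",
              length(x$genes), min(K), max(K)))
  cat(sprintf("  total mRNA %.6g, total ribosomes %.6g\n",
              x$total_mrna, x$total_ribosomes))
  invisible(x)
}

#' Generate a heterologous reporter gene
#'
#' A GFP-like stand-in: exactly \code{protein_length} uniformly drawn sense
#' codons (239 by default, the GFP ORF length excluding the stop codon),
#' mRNA level 0 (set later by the experiment drivers) and initiation rate
#' 0.8/s (the genome median).
#'
#' @param protein_length ORF length in codons (\eqn{\ge 25}).
#' @param seed integer seed.
#' @return a \code{gene_record}.
#' @export
generate_reporter <- function(protein_length = 239L, seed = 1L) {
  stopifnot(protein_length >= 25)
  set.seed(as.integer(seed))
  gene_record("reporter",
              sample(sense_codons(), protein_length, replace = TRUE),
              mrna_level = 0, initiation_rate = 0.8)
}

# ---- plain-text interchange -------------------------------------------------

#' Write / read ORFs as FASTA
#'
#' One record per gene; the sequence is the nucleotide coding sequence
#' (codons concatenated, no stop codon).
#'
#' @param genome a \code{genome} object.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- vapply(genome$genes, function(g) paste(g$orf, collapse = ""), "")
  names(seqs) <- vapply(genome$genes, `[[`, "", "gene_id")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @param path FASTA of coding sequences; length must be divisible by 3; a
#'   trailing stop codon is trimmed with a message.
#' @return named list of codon vectors.
#' @export
read_orf_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(ss), function(i) {
    s <- as.character(ss[[i]])
    if (nchar(s) %% 3 != 0)
      stop("sequence length not divisible by 3: ", names(ss)[i])
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    k <- length(cod)
    if (cod[k] %in% stop_codons) {
      message("trimming trailing stop codon from ", names(ss)[i])
      cod <- cod[-k]
    }
    if (any(cod %in% stop_codons))
      stop("internal stop codon in ", names(ss)[i])
    cod
  })
  names(out) <- names(ss)
  out
}

#' Write / read the per-gene table as TSV
#'
#' Columns \code{gene_id}, \code{mrna_level}, \code{initiation_rate}.
#' @param genome a \code{genome}.
#' @param path file path.
#' @export
write_gene_table <- function(genome, path) {
  df <- data.frame(
    gene_id = vapply(genome$genes, `[[`, "", "gene_id"),
    mrna_level = vapply(genome$genes, `[[`, 0, "mrna_level"),
    initiation_rate = vapply(genome$genes, `[[`, 0, "initiation_rate"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "numeric", "numeric"))
}

#' Write / read a codon decoding-time table as TSV
#'
#' Columns \code{codon}, \code{decoding_time_s}.
#' @param table a \code{codon_table}.
#' @param path file path.
#' @export
write_codon_table <- function(table, path) {
  df <- data.frame(codon = names(table$tau),
                   decoding_time_s = unname(table$tau))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_codon_table
#' @export
read_codon_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric"))
  tau <- df$decoding_time_s
  names(tau) <- df$codon
  tau <- tau[sense_codons()]
  tab <- structure(list(tau = tau, groups = synonymous_groups()),
                   class = "codon_table")
  validate_codon_table(tab)
}

#' Reassemble a genome from its FASTA and gene-table files
#'
#' @param fasta path of the ORF FASTA.
#' @param gene_tsv path of the gene table TSV.
#' @param total_ribosomes pool size \eqn{H_0}.
#' @return a \code{genome}.
#' @export
read_genome <- function(fasta, gene_tsv, total_ribosomes = 200000) {
  orfs <- read_orf_fasta(fasta)
  tab <- read_gene_table(gene_tsv)
  stopifnot(setequal(names(orfs), tab$gene_id))
  genes <- lapply(seq_len(nrow(tab)), function(i) {
    gene_record(tab$gene_id[i], orfs[[tab$gene_id[i]]],
                tab$mrna_level[i], tab$initiation_rate[i])
  })
  structure(list(genes = genes, total_mrna = sum(tab$mrna_level),
                 total_ribosomes = total_ribosomes),
            class = "genome")
}
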