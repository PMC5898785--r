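#' Partition an ORF into coarse-grained chain pieces
#'
#' An ORF of \code{K} codons is split into \eqn{n+1} contiguous pieces: the
#' first piece has \eqn{q-1} codons (it is absorbed into the initiation
#' rate, reflecting late initiation stages), pieces 2..\eqn{n} have \eqn{q}
#' codons each, and the last piece has between \eqn{q/2} and \eqn{3q/2}
#' codons. The number of post-first pieces is chosen by half-up rounding of
#' \eqn{(K - q + 1)/q}, which resolves a last piece of exactly \eqn{3q/2}
#' codons toward one extra site of \eqn{q/2}. The chain dimension is
#' \eqn{n} = number of pieces minus one.
#'
#' @param K ORF length in codons (stop excluded).
#' @param q codons per site; even, \eqn{\ge 2}; default 10 (about one
#'   ribosome footprint).
#' @return object of class \code{piece_partition}: list with \code{q},
#'   \code{piece_sizes} (length \eqn{n+1}) and \code{n}.
#' @examples
#' partition_orf(146)  # sizes 9, 10 x 13, 7; n = 14
#' @export
partition_orf <- function(K, q = 10L) {
  stopifnot(q >= 2, q %% 2 == 0)
  K <- as.integer(K)
  q <- as.integer(q)
  r <- K - (q - 1L)
  if (r < q / 2)
    stop("K = ", K, " too small: the last piece needs at least q/2 codons")
  m <- max(1L, as.integer(floor(r / q + 0.5)))
  last <- r - (m - 1L) * q
  sizes <- c(q - 1L, rep(q, m - 1L), last)
  stopifnot(last >= q / 2, last <= 3 * q / 2, sum(sizes) == K)
  structure(list(q = as.integer(q), piece_sizes = sizes, n = m),
            class = "piece_partition")
}

# 1-based codon index ranges of each piece
piece_ranges <- function(part) {
  ends <- cumsum(part$piece_sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  cbind(start = starts, end = ends)
}

#' Map an ORF to chain rates
#'
#' Each elongation/exit rate \eqn{\lambda_i} (\eqn{i \ge 1}) is the
#' reciprocal of the summed decoding times of piece \eqn{i+1}; the
#' initiation rate folds the initiation event and the first piece:
#' \eqn{\lambda_0 = 1/(p^{-1} + \sum_{k=1}^{q-1}\tau_k)} where \eqn{p} is
#' the gene's initiation rate.
#'
#' @param gene a \code{gene_record}.
#' @param table a \code{codon_table}.
#' @param q codons per site (default 10).
#' @return an \code{rfmio_spec} with \code{copy_weight} set to the gene's
#'   mRNA level.
#' @export
rates_from_orf <- function(gene, table, q = 10L) {
  tau <- table$tau[gene$orf]
  if (anyNA(tau))
    stop("codon(s) absent from table: ",
         paste(unique(gene$orf[is.na(tau)]), collapse = ", "))
  part <- partition_orf(length(gene$orf), q)
  rng <- piece_ranges(part)
  piece_tau <- vapply(seq_len(nrow(rng)),
                      function(i) sum(tau[rng[i, 1]:rng[i, 2]]), 0)
  lambda <- c(1 / (1 / gene$initiation_rate + piece_tau[1]),
              1 / piece_tau[-1])
  rfmio_spec(lambda, copy_weight = gene$mrna_level, gene_id = gene$gene_id)
}

#' Normalize decoding times against a genome
#'
#' Rescales all decoding times by one constant so that the median
#' per-gene codon elongation rate \eqn{K_g / \sum_k \tau_k(g)} over the
#' genome equals \code{target} codons per second (lower-median convention
#' for an even gene count). \code{by = "codon"} instead matches the median
#' per-codon rate \eqn{1/\tau} over the table, an alternative reading of
#' the calibration.
#'
#' @param table a \code{codon_table}.
#' @param genome a \code{genome} (used for \code{by = "gene"}).
#' @param target target median elongation rate, codons/s (default 6.4).
#' @param by \code{"gene"} (default) or \code{"codon"}.
#' @return the rescaled \code{codon_table}.
#' @export
normalize_decoding_times <- function(table, genome, target = 6.4,
                                     by = c("gene", "codon")) {
  by <- match.arg(by)
  if (by == "gene") {
    stopifnot(length(genome$genes) >= 1)
    rate_g <- vapply(genome$genes, function(g) {
      length(g$orf) / sum(table$tau[g$orf])
    }, 0)
    s <- median_low(rate_g) / target
  } else {
    s <- median_low(1 / table$tau) / target
  }
  table$tau <- table$tau * s
  table
}

#' Estimate initiation rates from density and mRNA level
#'
#' When initiation is rate limiting, ribosome density per mRNA copy is
#' approximately proportional to the initiation rate; this sets
#' \eqn{p_g = \kappa\, \mathrm{density}_g / \mathrm{mrna}_g} with
#' \eqn{\kappa} chosen so the median \eqn{p} equals \code{target_median}.
#'
#' @param density per-gene ribosome densities (positive).
#' @param mrna per-gene mRNA levels (positive).
#' @param target_median target median initiation rate (default 0.8/s).
#' @return numeric vector of initiation rates.
#' @examples
#' estimate_initiation(c(2, 4, 8), c(1, 1, 1))  # 0.4 0.8 1.6
#' @export
estimate_initiation <- function(density, mrna, target_median = 0.8) {
  stopifnot(length(density) == length(mrna),
            all(density > 0), target_median > 0)
  if (any(mrna <= 0)) stop("zero or negative mRNA level")
  raw <- density / mrna
  raw * (target_median / median_low(raw))
}
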