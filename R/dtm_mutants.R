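#' Decoding-time measure of an ORF
#'
#' Scores how far an ORF is from its fastest synonymous recoding:
#' \eqn{\eta = \sum_i (\tau_i - \psi(i))\, w_i / K}, where \eqn{\psi(i)} is
#' the minimal decoding time within the synonymous group of codon \eqn{i}.
#' Zero means every codon is already the fastest synonym; larger values
#' mean slower codons are used.
#'
#' @param orf character vector of codons.
#' @param table a \code{codon_table}.
#' @param weights positive weights, one per codon; defaults to homogeneous
#'   (all 1).
#' @return \eqn{\eta \ge 0}, in seconds.
#' @export
dtm <- function(orf, table, weights = default_weights(length(orf))) {
  K <- length(orf)
  stopifnot(length(weights) == K, all(weights > 0))
  tau <- table$tau[orf]
  if (anyNA(tau)) stop("codon(s) absent from table")
  psi <- group_min_tau(table)[orf]
  sum((tau - psi) * weights) / K
}

# per-codon minimal tau over its synonymous group, named by codon
group_min_tau <- function(table) {
  out <- numeric(length(table$tau))
  names(out) <- names(table$tau)
  for (g in table$groups) out[g] <- min(table$tau[g])
  out
}

#' Default weight profiles for the decoding-time measure
#'
#' Homogeneous weights treat all positions equally; monotone-increasing
#' weights encode the hypothesis that slow codons near the 3' end cause
#' larger ribosomal traffic jams. The increasing profile is a linear ramp
#' \eqn{w_i = 2i/(K+1)} with mean exactly 1, so the two profiles are
#' directly comparable.
#'
#' @param K ORF length in codons.
#' @param kind \code{"homogeneous"} (default) or \code{"increasing"}.
#' @return numeric weight vector of length \code{K}.
#' @export
default_weights <- function(K, kind = c("homogeneous", "increasing")) {
  kind <- match.arg(kind)
  stopifnot(K >= 1)
  switch(kind,
         homogeneous = rep(1, K),
         increasing = 2 * seq_len(K) / (K + 1))
}

# speed-class representative within a synonymous group: fastest, slowest,
# or the median-time codon (lower-middle for even group sizes); ties break
# on alphabetical codon order for determinism
class_codon <- function(table, speed) {
  vapply(table$groups, function(g) {
    tau <- table$tau[g]
    ord <- order(tau, g)
    switch(speed,
           fast = g[ord[1L]],
           slow = g[ord[length(g)]],
           median = g[ord[ceiling(length(g) / 2)]])
  }, "")
}

#' Region rules for synonymous variants
#'
#' The five built-in designs for a reporter of length \code{K}:
#' \describe{
#'   \item{HIGH_RD}{5' half fast, 3' half slow: ribosomes enter quickly and
#'     queue behind the slow tail (high density, "traffic jam").}
#'   \item{LOW_RD}{5' half slow, 3' half fast (low density, free flow).}
#'   \item{MDN_RD}{first third slow, middle third median, last third fast.}
#'   \item{SPD_TR}{all fast (maximal translation rate; \eqn{\eta = 0}).}
#'   \item{SLW_TR}{all slow (minimal translation rate; maximal \eqn{\eta}).}
#' }
#' For \code{K = 239} the half split is at codons 1-119 / 120-239 and the
#' thirds at 1-79 / 80-159 / 160-239 (aligned with the q = 10 chain
#' pieces); other lengths split at \eqn{\lceil K/2 \rceil} and thirds.
#'
#' @param name one of \code{"HIGH_RD"}, \code{"LOW_RD"}, \code{"MDN_RD"},
#'   \code{"SPD_TR"}, \code{"SLW_TR"}.
#' @param K ORF length.
#' @return object of class \code{variant_rule}: list with \code{name} and
#'   \code{region_map}, a data frame of \code{start}, \code{end},
#'   \code{speed}.
#' @export
variant_rule <- function(name = c("HIGH_RD", "LOW_RD", "MDN_RD",
                                  "SPD_TR", "SLW_TR"), K) {
  name <- match.arg(name)
  stopifnot(K >= 3)
  half <- ceiling(K / 2) - 1L           # K = 239 -> 119
  b1 <- floor(K / 3)                    # K = 239 -> 79
  b2 <- b1 + ceiling((K - b1) / 2)      # K = 239 -> 159
  region_map <- switch(name,
    HIGH_RD = data.frame(start = c(1L, half + 1L), end = c(half, K),
                         speed = c("fast", "slow")),
    LOW_RD = data.frame(start = c(1L, half + 1L), end = c(half, K),
                        speed = c("slow", "fast")),
    MDN_RD = data.frame(start = c(1L, b1 + 1L, b2 + 1L),
                        end = c(b1, b2, K),
                        speed = c("slow", "median", "fast")),
    SPD_TR = data.frame(start = 1L, end = K, speed = "fast"),
    SLW_TR = data.frame(start = 1L, end = K, speed = "slow"))
  structure(list(name = name, region_map = region_map, K = as.integer(K)),
            class = "variant_rule")
}

#' Design a synonymous variant of an ORF
#'
#' Replaces each codon by the representative of its synonymous group for
#' the speed class of its region (fast = minimal decoding time, slow =
#' maximal, median = middle). The amino-acid sequence is preserved and the
#' operation is idempotent.
#'
#' @param orf character vector of codons.
#' @param table a \code{codon_table}.
#' @param rule a \code{variant_rule} (or a rule name, resolved at the
#'   ORF's length).
#' @return the recoded codon vector.
#' @export
design_variant <- function(orf, table, rule) {
  K <- length(orf)
  if (is.character(rule)) rule <- variant_rule(rule, K)
  stopifnot(inherits(rule, "variant_rule"), rule$K == K)
  rm <- rule$region_map
  covered <- integer(0)
  for (i in seq_len(nrow(rm))) covered <- c(covered, rm$start[i]:rm$end[i])
  stopifnot(identical(sort(covered), seq_len(K)))
  aa <- codon_to_aa()
  out <- orf
  for (i in seq_len(nrow(rm))) {
    reps <- class_codon(table, rm$speed[i])
    idx <- rm$start[i]:rm$end[i]
    out[idx] <- reps[aa[orf[idx]]]
  }
  stopifnot(identical(unname(aa[out]), unname(aa[orf])))
  out
}

#' Tabulate variant properties of a reporter
#'
#' For the original ORF and each of the five built-in variants: the
#' homogeneous and increasing-weight decoding-time measures, and the
#' single-chain steady-state mean density and translation rate at
#' initiation rate \code{alpha} and unit input.
#'
#' @param orf reporter codon vector.
#' @param table a \code{codon_table}.
#' @param alpha initiation rate used for the steady state (default 0.8).
#' @param q codons per site.
#' @return data frame with one row per variant: \code{variant},
#'   \code{eta}, \code{eta_inc}, \code{rho}, \code{R}.
#' @export
variant_table <- function(orf, table, alpha = 0.8, q = 10L) {
  K <- length(orf)
  variants <- c(original = NA, HIGH_RD = "HIGH_RD", LOW_RD = "LOW_RD",
                MDN_RD = "MDN_RD", SPD_TR = "SPD_TR", SLW_TR = "SLW_TR")
  rows <- lapply(names(variants), function(v) {
    seq_v <- if (v == "original") orf else
      design_variant(orf, table, variants[[v]])
    g <- gene_record(paste0("reporter_", v), seq_v, 0, alpha)
    ss <- steady_state_chain(rates_from_orf(g, table, q), u = 1)
    data.frame(variant = v,
               eta = dtm(seq_v, table),
               eta_inc = dtm(seq_v, table,
                             default_weights(K, "increasing")),
               rho = ss$rho, R = ss$R)
  })
  do.call(rbind, rows)
}
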