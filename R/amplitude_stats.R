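#' Mean and amplitude of a periodic signal
#'
#' Amplitude is half the peak-to-peak excursion over the sampled period;
#' for sinusoidal forcing this equals the first Fourier coefficient up to
#' grid error.
#'
#' @param samples numeric vector of \eqn{\ge 8} samples over one period.
#' @return list with \code{mean} and \code{amplitude}.
#' @export
period_stats <- function(samples) {
  if (length(samples) < 8) stop("need at least 8 samples over the period")
  list(mean = mean(samples),
       amplitude = (max(samples) - min(samples)) / 2)
}

# population variance (divide by m): the gene set is the full population
var_pop <- function(x) mean((x - mean(x))^2)

#' Amplitude statistics of an entrained trajectory
#'
#' Computes, over the genes not in \code{exclude}: the per-gene translation
#' rate amplitude \eqn{R_a^i = 100\,\mathrm{amp}(R^i)/\mathrm{mean}(R^i)}
#' and density amplitude \eqn{\rho_a^i} (both percent of the gene's period
#' mean), their gene-wise means \eqn{\bar R_a, \bar\rho_a} and population
#' variances \eqn{\hat R_a, \hat\rho_a}; and for the pool: \eqn{\bar z}
#' (mean free pool, percent of \eqn{H_0}) and \eqn{z_a} (pool amplitude,
#' percent of the mean free pool).
#'
#' @param traj a \code{periodic_trajectory}.
#' @param H0 total ribosome count (defaults to the one recorded in the
#'   trajectory).
#' @param exclude gene ids to drop from the gene-wise statistics; by
#'   default the oscillating (modulated-group) chains, i.e. the statistics
#'   describe the effect on the rest of the genes.
#' @return object of class \code{amplitude_stats}: list with \code{zbar},
#'   \code{z_a}, \code{Rbar_a}, \code{rhobar_a}, \code{Rhat_a},
#'   \code{rhohat_a}, \code{per_gene} (data frame of gene id, \code{R_a},
#'   \code{rho_a}) and \code{m} (number of genes summarized).
#' @export
summarize_amplitudes <- function(traj, H0 = traj$H0, exclude = NULL) {
  stopifnot(inherits(traj, "periodic_trajectory"))
  if (is.null(exclude)) {
    base_of <- sub("_mod$", "", traj$gene_ids)
    exclude <- unique(base_of[traj$modulated])
  }
  keep <- !(sub("_mod$", "", traj$gene_ids) %in% exclude)
  zs <- period_stats(traj$z)
  zbar <- 100 * zs$mean / H0
  z_a <- 100 * zs$amplitude / zs$mean
  if (!any(keep)) {
    per <- data.frame(gene_id = character(0), R_a = numeric(0),
                      rho_a = numeric(0))
    return(structure(list(zbar = zbar, z_a = z_a, Rbar_a = NA_real_,
                          rhobar_a = NA_real_, Rhat_a = NA_real_,
                          rhohat_a = NA_real_, per_gene = per, m = 0L),
                     class = "amplitude_stats"))
  }
  amp_pct <- function(mat) {
    apply(mat[, keep, drop = FALSE], 2, function(s) {
      st <- period_stats(s)
      if (st$mean <= 0) stop("gene with zero mean signal")
      100 * st$amplitude / st$mean
    })
  }
  R_a <- amp_pct(traj$R)
  rho_a <- amp_pct(traj$rho)
  structure(list(zbar = zbar, z_a = z_a,
                 Rbar_a = mean(R_a), rhobar_a = mean(rho_a),
                 Rhat_a = var_pop(R_a), rhohat_a = var_pop(rho_a),
                 per_gene = data.frame(gene_id = traj$gene_ids[keep],
                                       R_a = unname(R_a),
                                       rho_a = unname(rho_a)),
                 m = sum(keep)),
            class = "amplitude_stats")
}

#' @export
print.amplitude_stats <- function(x, ...) {
  cat(sprintf(
    "amplitude stats over %d genes:\n  zbar %.4g%%  z_a %.4g%%  Rbar_a %.4g%%  rhobar_a %.4g%%\n  Rhat_a %.4g  rhohat_a %.4g\n",
    x$m, x$zbar, x$z_a, x$Rbar_a, x$rhobar_a, x$Rhat_a, x$rhohat_a))
  invisible(x)
}

#' @export
as.data.frame.amplitude_stats <- function(x, ...) {
  data.frame(zbar = x$zbar, z_a = x$z_a, Rbar_a = x$Rbar_a,
             rhobar_a = x$rhobar_a, Rhat_a = x$Rhat_a,
             rhohat_a = x$rhohat_a, m = x$m)
}

#' Normalize a statistic per unit of oscillating mRNA
#'
#' Divides a statistic by the nominal oscillating mRNA level expressed as a
#' percentage of the total mRNA pool, giving the statistic per 1% of total
#' mRNA (per 600 mRNAs when the pool is 60,000); makes runs at different
#' nominal levels comparable.
#'
#' @param stat_value statistic (percent scale).
#' @param Lh_pct nominal level as percent of total mRNA (> 0).
#' @return normalized statistic.
#' @export
normalize_per_unit <- function(stat_value, Lh_pct) {
  stopifnot(all(Lh_pct > 0))
  stat_value / Lh_pct
}
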