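#' Oscillation specification
#'
#' Sinusoidal mRNA-level forcing of one or more target genes:
#' \eqn{\ell_h(t) = L_h (1 + A \sin(2\pi t/T + \phi))}.
#'
#' @param target_genes character vector of gene ids to oscillate.
#' @param L_h nominal mRNA level (copies) of each target; recycled.
#' @param A normalized amplitude in \eqn{[0, 1)}.
#' @param T forcing period, in model time units (seconds); default 16.
#' @param phase common phase offset, radians (default 0).
#' @return object of class \code{oscillation_spec}.
#' @export
oscillation_spec <- function(target_genes, L_h, A, T = 16, phase = 0) {
  stopifnot(A >= 0, A < 1, T > 0, all(L_h > 0))
  structure(list(target_genes = as.character(target_genes),
                 L_h = rep_len(L_h, length(target_genes)),
                 A = A, T = T, phase = phase),
            class = "oscillation_spec")
}

#' Instantaneous forced mRNA level
#'
#' @param t time (vectorized).
#' @param spec an \code{oscillation_spec}.
#' @return \eqn{L_h (1 + A \sin(2\pi t/T + \phi))}; when the spec targets
#'   several genes with different \eqn{L_h}, the first is used (they share
#'   amplitude, period and phase).
#' @export
mrna_level <- function(t, spec) {
  spec$L_h[1] * (1 + spec$A * sin(2 * pi * t / spec$T + spec$phase))
}

#' Split a forced gene into a baseline and a modulated chain
#'
#' A sinusoidally varying mRNA level between \eqn{\beta_1 = L_h(1-A)} and
#' \eqn{\beta_2 = L_h(1+A)} is realized, without creating or destroying
#' ribosomes, as \eqn{\beta_2} copies whose initiation is periodically
#' gated: a baseline chain of constant weight \eqn{\beta_1} plus a
#' modulated chain of weight \eqn{\beta_2 - \beta_1 = 2 A L_h} whose
#' initiation input is multiplied by
#' \eqn{m(t) = (1 + \sin(2\pi t/T + \phi))/2}, so the effective
#' initiation-weighted copy number is exactly \eqn{\ell_h(t)} at all times.
#' Both chains share the elongation rates.
#'
#' @param spec_rfmio the gene's \code{rfmio_spec} (copy weight ignored).
#' @param L_h nominal mRNA level.
#' @param A amplitude in \eqn{[0, 1)}.
#' @param T period.
#' @param phase phase offset, radians.
#' @return list of \code{rfmio_spec}: baseline and (when \eqn{A > 0})
#'   modulated.
#' @export
build_modulated_group <- function(spec_rfmio, L_h, A, T = 16, phase = 0) {
  stopifnot(A >= 0, A < 1, L_h > 0, T > 0)
  base <- rfmio_spec(spec_rfmio$lambda, copy_weight = L_h * (1 - A),
                     gene_id = spec_rfmio$gene_id)
  if (A == 0) {
    base$copy_weight <- L_h
    return(list(base))
  }
  m <- local({
    T_ <- T; ph <- phase
    function(t) (1 + sin(2 * pi * t / T_ + ph)) / 2
  })
  mod <- rfmio_spec(spec_rfmio$lambda, copy_weight = 2 * A * L_h,
                    modulation = m,
                    gene_id = paste0(spec_rfmio$gene_id, "_mod"))
  list(base, mod)
}

#' Simulate until entrained to the forcing period
#'
#' Starts from the unforced network steady state (modulations frozen at
#' their mean) and integrates period by period; after each period the state
#' sampled on the period grid is compared with the previous period
#' (max-norm, pool occupancy scaled by its magnitude). Entrainment theory
#' for the pooled network guarantees convergence of every state variable to
#' a period-\eqn{T} orbit.
#'
#' @param specs list of \code{rfmio_spec} (including modulated chains).
#' @param pool a \code{pool_spec}.
#' @param T forcing period.
#' @param tol entrainment tolerance on the period-map residual
#'   (default 1e-6).
#' @param max_periods iteration budget (default 200).
#' @param samples_per_period grid resolution of the returned period
#'   (default 128).
#' @param rtol,atol integrator tolerances.
#' @return object of class \code{periodic_trajectory}: list with
#'   \code{time} (one period, \code{samples_per_period + 1} points),
#'   \code{z}, matrices \code{R} and \code{rho} (time x chain),
#'   \code{gene_ids}, \code{modulated} (logical per chain),
#'   \code{residual}, \code{periods}, and the final flattened states.
#' @export
simulate_entrained <- function(specs, pool, T = 16, tol = 1e-6,
                               max_periods = 200L,
                               samples_per_period = 128L,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(T > 0, samples_per_period >= 8)
  net <- compile_network(specs, pool)
  st0 <- solve_network_steady(specs, pool)
  y <- flatten_state(st0)
  grid <- seq(0, T, length.out = samples_per_period + 1L)
  scale <- c(rep(1, net$N), max(abs(y[net$N + 1L]), 1))
  prev <- NULL
  residual <- Inf
  residuals <- numeric(0)
  sol <- NULL
  for (k in seq_len(max_periods)) {
    sol <- deSolve::ode(y, grid + (k - 1) * T, network_rhs_flat, net,
                        method = "adams", rtol = rtol, atol = atol)
    samp <- sol[, -1, drop = FALSE]
    y <- samp[nrow(samp), ]
    if (!is.null(prev)) {
      residual <- max(abs(samp - prev) / rep(scale, each = nrow(samp)))
      residuals <- c(residuals, residual)
      if (residual < tol) break
    }
    prev <- samp
  }
  if (residual >= tol)
    stop(sprintf(
      "no entrainment within %d periods (last period-map residual %.3g)",
      max_periods, residual))
  x <- sol[, 1L + seq_len(net$N), drop = FALSE]
  lamn <- vapply(specs, function(s) s$lambda[s$n + 1L], 0)
  R <- sapply(seq_along(specs), function(j) lamn[j] * x[, net$ends[j]])
  rho <- sapply(seq_along(specs), function(j)
    rowMeans(x[, net$starts[j]:net$ends[j], drop = FALSE]))
  ids <- vapply(specs, `[[`, "", "gene_id")
  structure(list(time = grid,
                 z = unname(sol[, net$N + 2L]),
                 R = matrix(R, nrow = nrow(sol)),
                 rho = matrix(rho, nrow = nrow(sol)),
                 gene_ids = ids,
                 modulated = !vapply(lapply(specs, `[[`, "modulation"),
                                     is.null, TRUE),
                 copy_weights = vapply(specs, `[[`, 0, "copy_weight"),
                 residual = residual, residuals = residuals,
                 periods = k, H0 = pool$H0),
            class = "periodic_trajectory")
}

#' @export
print.periodic_trajectory <- function(x, ...) {
  cat(sprintf(
    "entrained trajectory: %d chains, %d periods, residual %.3g\n",
    ncol(x$R), x$periods, x$residual))
  invisible(x)
}

#' Export a periodic trajectory as CSV
#'
#' @param traj a \code{periodic_trajectory}.
#' @param path output CSV.
#' @return the data frame, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time = traj$time, z = traj$z,
                   traj$R, traj$rho, check.names = FALSE)
  names(df) <- c("time", "z", paste0("R_", traj$gene_ids),
                 paste0("rho_", traj$gene_ids))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
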