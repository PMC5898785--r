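#' Experiment configuration
#'
#' Bundles a synthetic genome recipe with the oscillation grid. The
#' desk-scale default keeps the ribosome:mRNA economy of the whole-cell
#' parameterization by scaling the pools with the gene count:
#' \eqn{H_0 = 200000\, m/6310} and \eqn{L_T = 60000\, m/6310}.
#'
#' @param n_genes synthetic genome size (default 50).
#' @param seed master seed; recorded in all outputs.
#' @param A normalized forcing amplitude (default 1/2).
#' @param T forcing period (default 16).
#' @param zbar_target mean free pool target, percent of \eqn{H_0}
#'   (default 30).
#' @param alpha reporter initiation rate (default 0.8).
#' @param Lh_pct reporter nominal mRNA level, percent of total mRNA
#'   (default 20).
#' @param set_sizes oscillating-set sizes for the endogenous experiment.
#' @param repetitions random-set repetitions (default 30).
#' @param length_range,mrna_sdlog,spread passed to the generators.
#' @param samples_per_period,entrain_tol,max_periods entrainment controls.
#' @return classed list \code{experiment_config}.
#' @export
experiment_config <- function(n_genes = 50L, seed = 1L, A = 0.5, T = 16,
                              zbar_target = 30, alpha = 0.8, Lh_pct = 20,
                              set_sizes = c(1L, 5L, 10L),
                              repetitions = 30L,
                              length_range = c(25L, 4911L),
                              mrna_sdlog = 1.5, spread = 0.5,
                              samples_per_period = 128L,
                              entrain_tol = 1e-6, max_periods = 200L) {
  structure(list(n_genes = n_genes, seed = seed, A = A, T = T,
                 zbar_target = zbar_target, alpha = alpha,
                 Lh_pct = Lh_pct, set_sizes = set_sizes,
                 repetitions = repetitions, length_range = length_range,
                 mrna_sdlog = mrna_sdlog, spread = spread,
                 samples_per_period = samples_per_period,
                 entrain_tol = entrain_tol, max_periods = max_periods,
                 H0 = 200000 * n_genes / 6310,
                 L_T = 60000 * n_genes / 6310),
            class = "experiment_config")
}

# genome + normalized table + per-gene chain specs for a config
build_system <- function(config) {
  genome <- generate_genome(config$n_genes, seed = config$seed,
                            length_range = config$length_range,
                            total_mrna = config$L_T,
                            total_ribosomes = config$H0,
                            mrna_sdlog = config$mrna_sdlog)
  table <- generate_codon_table(seed = config$seed + 1L,
                                spread = config$spread)
  table <- normalize_decoding_times(table, genome)
  specs <- lapply(genome$genes, rates_from_orf, table = table)
  list(genome = genome, table = table, specs = specs)
}

# replace the chains of the oscillating genes by modulated groups
apply_oscillation <- function(specs, genome, osc_ids, A, T) {
  ids <- vapply(specs, `[[`, "", "gene_id")
  out <- list()
  for (j in seq_along(specs)) {
    if (ids[j] %in% osc_ids) {
      L_h <- specs[[j]]$copy_weight
      out <- c(out, build_modulated_group(specs[[j]], L_h, A, T))
    } else out <- c(out, specs[j])
  }
  out
}

entrain_and_summarize <- function(specs, pool, config) {
  traj <- simulate_entrained(specs, pool, T = config$T,
                             tol = config$entrain_tol,
                             max_periods = config$max_periods,
                             samples_per_period = config$samples_per_period)
  summarize_amplitudes(traj)
}

#' Oscillate endogenous gene sets
#'
#' For each set size \eqn{p}: in \code{"sorted"} mode the \eqn{p} genes
#' with the largest mRNA levels oscillate (an upper bound on the effect of
#' any \eqn{p}-gene set); in \code{"random"} mode \code{repetitions}
#' independent \eqn{p}-gene subsets are drawn and each statistic is
#' averaged across repetitions. Statistics are computed over the
#' non-oscillating genes.
#'
#' @param config an \code{experiment_config}.
#' @param modes subset of \code{c("sorted", "random")}.
#' @return data frame, one row per (mode, p): amplitude statistics plus
#'   bookkeeping columns (\code{A}, \code{T}, \code{seed}).
#' @export
run_endogenous <- function(config, modes = c("sorted", "random")) {
  modes <- match.arg(modes, several.ok = TRUE)
  sys <- build_system(config)
  mrna <- vapply(sys$genome$genes, `[[`, 0, "mrna_level")
  ids <- vapply(sys$genome$genes, `[[`, "", "gene_id")
  if (any(config$set_sizes > length(ids)))
    stop("oscillating-set size exceeds the genome size")
  pool0 <- calibrate_pool(sys$specs, config$H0, config$zbar_target)
  one_run <- function(osc_ids) {
    specs <- apply_oscillation(sys$specs, sys$genome, osc_ids,
                               config$A, config$T)
    entrain_and_summarize(specs, pool0, config)
  }
  rows <- list()
  for (mode in modes) for (p in config$set_sizes) {
    if (mode == "sorted") {
      st <- one_run(ids[order(mrna, decreasing = TRUE)[seq_len(p)]])
      df <- as.data.frame(st)
    } else {
      reps <- lapply(seq_len(config$repetitions), function(r) {
        set.seed(config$seed + 1000L * r + p)
        as.data.frame(one_run(sample(ids, p)))
      })
      df <- do.call(rbind, reps)
      df <- as.data.frame(lapply(df, mean))
    }
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(mode = mode, p = p), df,
            data.frame(A = config$A, T = config$T, seed = config$seed))
  }
  do.call(rbind, rows)
}

#' Oscillate a heterologous reporter over a parameter grid
#'
#' For every grid point (\code{A}, \code{Lh_pct}, \code{alpha},
#' \code{zbar}): the reporter's copy number is set to
#' \eqn{L_h = \tilde L_h L_T / 100}, the pool response is calibrated to the
#' \eqn{\bar z} target with the reporter present at its nominal level, the
#' reporter's mRNA level is forced sinusoidally, and the entrained
#' amplitude statistics over the endogenous genes are collected. Normalized
#' columns (statistic per 1% of total mRNA) are appended.
#'
#' @param config an \code{experiment_config}.
#' @param reporter a \code{gene_record} (default: generated 239-codon
#'   reporter).
#' @param variant \code{"original"} or one of the five variant-rule names;
#'   applied to the reporter ORF before mapping.
#' @param A_grid,Lh_grid,alpha_grid,zbar_grid grid values; default to the
#'   single values in \code{config}.
#' @return data frame, one row per grid point.
#' @export
run_heterologous <- function(config, reporter = NULL, variant = "original",
                             A_grid = config$A, Lh_grid = config$Lh_pct,
                             alpha_grid = config$alpha,
                             zbar_grid = config$zbar_target) {
  sys <- build_system(config)
  if (is.null(reporter))
    reporter <- generate_reporter(seed = config$seed + 2L)
  orf <- reporter$orf
  if (variant != "original")
    orf <- design_variant(orf, sys$table, variant)
  rows <- list()
  for (alpha in alpha_grid) for (zb in zbar_grid) for (Lh in Lh_grid) {
    L_h <- Lh * config$L_T / 100
    gene <- gene_record("reporter", orf, L_h, alpha)
    rep_spec <- rates_from_orf(gene, sys$table)
    # calibrate once per cell state (reporter at its nominal level),
    # then vary the forcing amplitude in that fixed cell
    pool <- calibrate_pool(c(sys$specs, list(rep_spec)), config$H0, zb)
    for (A in A_grid) {
      group <- build_modulated_group(rep_spec, L_h, A, config$T)
      specs <- c(sys$specs, group)
      st <- entrain_and_summarize(specs, pool, config)
      df <- as.data.frame(st)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(variant = variant, A = A, T = config$T, Lh_pct = Lh,
                   alpha = alpha, zbar_target = zb, seed = config$seed),
        df,
        data.frame(z_a_norm = normalize_per_unit(df$z_a, Lh),
                   Rbar_a_norm = normalize_per_unit(df$Rbar_a, Lh),
                   rhobar_a_norm = normalize_per_unit(df$rhobar_a, Lh)))
    }
  }
  do.call(rbind, rows)
}

#' Sweep the mean free ribosomal pool
#'
#' Repeats the heterologous experiment at fixed (\code{A}, \code{T},
#' \code{alpha}, \code{Lh_pct}) for several \eqn{\bar z} targets.
#'
#' @param config an \code{experiment_config}.
#' @param zbar_grid \eqn{\bar z} targets in percent (default
#'   \code{c(10, 15, 20, 25, 30)}).
#' @param variant reporter variant name (default \code{"HIGH_RD"}).
#' @param reporter optional \code{gene_record}.
#' @return data frame, one row per \eqn{\bar z}.
#' @export
run_zbar_sweep <- function(config, zbar_grid = c(10, 15, 20, 25, 30),
                           variant = "HIGH_RD", reporter = NULL) {
  run_heterologous(config, reporter = reporter, variant = variant,
                   zbar_grid = zbar_grid)
}
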