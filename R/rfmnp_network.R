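#' Pool specification
#'
#' The free-ribosome pool couples all chains: chain \eqn{j} receives input
#' \eqn{u^j = G(z)} where \eqn{G} vanishes at 0, is strictly increasing and
#' is linear near 0. Supported families: \code{"tanh"},
#' \eqn{G(z) = \tanh(z/c)}, and \code{"linear"}, \eqn{G(z) = z/c}.
#'
#' @param H0 total ribosome count (conserved).
#' @param G_family \code{"tanh"} (default) or \code{"linear"}.
#' @param c positive scale parameter of \eqn{G}.
#' @return object of class \code{pool_spec}.
#' @export
pool_spec <- function(H0, G_family = c("tanh", "linear"), c = H0) {
  G_family <- match.arg(G_family)
  stopifnot(H0 > 0, c > 0)
  structure(list(H0 = H0, G_family = G_family, c = c), class = "pool_spec")
}

pool_G <- function(pool, z) {
  switch(pool$G_family,
         tanh = tanh(z / pool$c),
         linear = z / pool$c)
}

#' Network state constructor
#'
#' @param x list of occupancy vectors, one per chain.
#' @param z free-pool occupancy (nonnegative).
#' @return object of class \code{network_state}.
#' @export
network_state <- function(x, z) {
  stopifnot(is.list(x), z >= 0)
  structure(list(x = x, z = z), class = "network_state")
}

# Precompute index structure for the flattened state vector
# (all chain sites concatenated, pool last).
compile_network <- function(specs, pool) {
  stopifnot(length(specs) >= 1, inherits(pool, "pool_spec"))
  n <- vapply(specs, `[[`, 0L, "n")
  N <- sum(n)
  ends <- cumsum(n)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lam_site <- unlist(lapply(specs, function(s) s$lambda[-1]))
  lam0 <- vapply(specs, function(s) s$lambda[1], 0)
  w <- vapply(specs, `[[`, 0, "copy_weight")
  mods <- lapply(specs, `[[`, "modulation")
  mod_idx <- which(!vapply(mods, is.null, TRUE))
  is_last <- logical(N); is_last[ends] <- TRUE
  list(m = length(specs), n = n, N = N, starts = starts, ends = ends,
       lam_site = lam_site, lam0 = lam0, w = w, w_site = rep(w, n),
       mods = mods, mod_idx = mod_idx, is_last = is_last, pool = pool)
}

# modulation factors at time t, one per chain (1 when unmodulated)
mod_values <- function(net, t) {
  v <- rep(1, net$m)
  for (j in net$mod_idx) v[j] <- net$mods[[j]](t)
  v
}

# flattened RHS used by the integrator
network_rhs_flat <- function(t, y, net) {
  N <- net$N
  x <- y[seq_len(N)]
  z <- y[N + 1L]
  G <- pool_G(net$pool, z)
  xnext <- c(x[-1L], 0)
  xnext[net$ends] <- 0
  out <- net$lam_site * x * (1 - xnext)
  inflow <- c(0, out[-N])
  u0 <- net$lam0 * mod_values(net, t) * (1 - x[net$starts]) * G
  inflow[net$starts] <- u0
  dz <- sum(net$w * out[net$ends]) - sum(net$w * u0)
  list(c(inflow - out, dz))
}

flatten_state <- function(state) c(unlist(state$x), state$z)

unflatten_state <- function(y, net) {
  x <- lapply(seq_len(net$m),
              function(j) y[net$starts[j]:net$ends[j]])
  network_state(x, y[net$N + 1L])
}

#' Time derivative of the pooled network
#'
#' Each chain receives input \eqn{u^j = G(z)} (times its initiation
#' modulation when present); the pool derivative is the sum of
#' copy-weighted chain outputs minus the copy-weighted binding flows
#' \eqn{\lambda_0^j (1 - x_1^j) G(z)}. The copy-weighted sum of all
#' derivatives is identically zero (ribosome conservation).
#'
#' @param state a \code{network_state}.
#' @param specs list of \code{rfmio_spec}.
#' @param pool a \code{pool_spec}.
#' @param t time (matters only for modulated chains).
#' @return list with \code{dx} (list of chain derivatives) and \code{dz}.
#' @export
network_rhs <- function(state, specs, pool, t = 0) {
  net <- compile_network(specs, pool)
  if (length(state$x) != net$m ||
      !all(lengths(state$x) == net$n))
    stop("state dimensions do not match specs")
  if (state$z < 0) stop("negative free pool")
  d <- network_rhs_flat(t, flatten_state(state), net)[[1]]
  dx <- lapply(seq_len(net$m),
               function(j) d[net$starts[j]:net$ends[j]])
  list(dx = dx, dz = d[net$N + 1L])
}

#' Total ribosome count of a network state
#'
#' \eqn{H = z + \sum_j w_j \sum_i x_i^j}; conserved along trajectories.
#'
#' @inheritParams network_rhs
#' @export
total_ribosomes <- function(state, specs) {
  w <- vapply(specs, `[[`, 0, "copy_weight")
  state$z + sum(w * vapply(state$x, sum, 0))
}

#' Steady state of the pooled network
#'
#' For a fixed pool occupancy \eqn{z} every chain has a unique steady state
#' at input \eqn{G(z)}; ribosome conservation
#' \eqn{z + \sum_j w_j \sum_i e_i^j(G(z)) = H_0} is strictly increasing in
#' \eqn{z}, so the network steady state reduces to one scalar root-find.
#' Chains with a modulation have it frozen at its time-average value 0.5
#' (the nominal mRNA level).
#'
#' @param specs list of \code{rfmio_spec}.
#' @param pool a \code{pool_spec}.
#' @param tol relative tolerance of the scalar root-find on \eqn{z}.
#' @return a \code{network_state} with an extra attribute \code{"R"}
#'   (per-chain steady translation rates).
#' @export
solve_network_steady <- function(specs, pool, tol = 1e-13) {
  H0 <- pool$H0
  modv <- vapply(specs, function(s) if (is.null(s$modulation)) 1 else 0.5, 0)
  warm <- vector("list", length(specs))   # warm starts across root iterations
  chains_at <- function(z) {
    G <- pool_G(pool, z)
    lapply(seq_along(specs), function(j) {
      s <- specs[[j]]
      ch <- steady_state_chain(s, u = G * modv[j], x0 = warm[[j]])
      warm[[j]] <<- ch$e
      ch
    })
  }
  w <- vapply(specs, `[[`, 0, "copy_weight")
  F <- function(z) {
    ch <- chains_at(z)
    z + sum(w * vapply(ch, function(c) sum(c$e), 0)) - H0
  }
  # F(0) = -H0 < 0, F(H0) >= 0, strictly increasing
  zr <- stats::uniroot(F, c(H0 * 1e-12, H0), tol = tol * H0)$root
  ch <- chains_at(zr)
  st <- network_state(lapply(ch, `[[`, "e"), zr)
  attr(st, "R") <- vapply(ch, `[[`, 0, "R")
  attr(st, "rho") <- vapply(ch, `[[`, 0, "rho")
  st
}

#' Calibrate the pool response scale to a target mean free pool
#'
#' Finds the scale \eqn{c} of \eqn{G} such that the unforced steady state
#' has \eqn{100\, z/H_0} equal to \code{target_zbar_pct}. The free pool
#' fraction is strictly increasing in \eqn{c} (a weaker pool response binds
#' fewer ribosomes), so the search is a bracketed root-find on
#' \eqn{\log c}.
#'
#' @param specs list of \code{rfmio_spec}.
#' @param H0 total ribosome count.
#' @param target_zbar_pct target mean free pool, percent of \eqn{H_0},
#'   in (0, 100).
#' @param G_family passed to \code{\link{pool_spec}}.
#' @param tol_pct tolerance on the achieved percentage (default 0.01).
#' @return the calibrated \code{pool_spec}.
#' @export
calibrate_pool <- function(specs, H0, target_zbar_pct,
                           G_family = "tanh", tol_pct = 0.01) {
  stopifnot(target_zbar_pct > 0, target_zbar_pct < 100)
  zbar_at <- function(logc) {
    p <- pool_spec(H0, G_family, c = exp(logc))
    st <- solve_network_steady(specs, p)
    100 * st$z / H0
  }
  lo <- log(H0) - 14; hi <- log(H0) + 14
  zlo <- zbar_at(lo); zhi <- zbar_at(hi)
  if (target_zbar_pct < zlo || target_zbar_pct > zhi)
    stop(sprintf(
      "target zbar %.4g%% outside achievable range [%.4g%%, %.4g%%]",
      target_zbar_pct, zlo, zhi))
  r <- stats::uniroot(function(l) zbar_at(l) - target_zbar_pct,
                      c(lo, hi), tol = 1e-10)
  p <- pool_spec(H0, G_family, c = exp(r$root))
  achieved <- zbar_at(r$root)
  if (abs(achieved - target_zbar_pct) > tol_pct)
    stop(sprintf("calibration stopped at %.4g%% (target %.4g%%)",
                 achieved, target_zbar_pct))
  p
}

#' Integrate the pooled network
#'
#' Adams (non-stiff) integration of the flattened network ODE at tight
#' tolerances; the rate constants are all of order 1/s so the system is
#' non-stiff.
#'
#' @param state initial \code{network_state}.
#' @param specs list of \code{rfmio_spec}.
#' @param pool a \code{pool_spec}.
#' @param times numeric vector of output times.
#' @param rtol,atol integrator tolerances.
#' @param maxsteps step budget per output interval.
#' @return matrix as returned by \code{deSolve::ode}: first column time,
#'   then chain sites (gene by gene), pool occupancy last.
#' @export
integrate_network <- function(state, specs, pool, times,
                              rtol = 1e-8, atol = 1e-10, maxsteps = 1e5) {
  net <- compile_network(specs, pool)
  y0 <- flatten_state(state)
  stopifnot(length(y0) == net$N + 1L)
  deSolve::ode(y0, times, network_rhs_flat, net,
               method = "adams", rtol = rtol, atol = atol,
               maxsteps = maxsteps)
}

#' Export a network trajectory as a tidy data frame / CSV
#'
#' Columns: \code{time}, \code{z}, and per-chain translation rate
#' \code{R_<id>} and mean density \code{rho_<id>}.
#'
#' @param sol matrix from \code{\link{integrate_network}}.
#' @param specs the specs used to produce it.
#' @param path optional CSV output path.
#' @return the data frame, invisibly when \code{path} is given.
#' @export
trajectory_frame <- function(sol, specs, path = NULL) {
  net <- compile_network(specs, pool_spec(1))
  ids <- vapply(seq_along(specs), function(j) {
    id <- specs[[j]]$gene_id
    if (is.na(id)) sprintf("chain%03d", j) else id
  }, "")
  x <- sol[, 1L + seq_len(net$N), drop = FALSE]
  lamn <- vapply(specs, function(s) s$lambda[s$n + 1L], 0)
  R <- sapply(seq_along(specs), function(j) lamn[j] * x[, net$ends[j]])
  rho <- sapply(seq_along(specs), function(j) {
    rowMeans(x[, net$starts[j]:net$ends[j], drop = FALSE])
  })
  R <- matrix(R, nrow = nrow(sol)); rho <- matrix(rho, nrow = nrow(sol))
  colnames(R) <- paste0("R_", ids); colnames(rho) <- paste0("rho_", ids)
  df <- data.frame(time = sol[, 1], z = sol[, net$N + 2L], R, rho,
                   check.names = FALSE)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
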