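#' Construct a ribosome-flow chain specification (RFMIO)
#'
#' An mRNA is modelled as a chain of \code{n} coarse-grained sites with
#' occupancies \eqn{x_i \in [0,1]} and \eqn{n+1} positive transition rates:
#' \eqn{\lambda_0} on the initiation side (scaled by the external input
#' \eqn{u}), \eqn{\lambda_1,\dots,\lambda_{n-1}} between sites and
#' \eqn{\lambda_n} at the exit. The exit flow \eqn{\lambda_n x_n} is the
#' translation rate.
#'
#' @param lambda numeric vector of \eqn{n+1} positive rates,
#'   \eqn{(\lambda_0,\dots,\lambda_n)}.
#' @param copy_weight nonnegative mRNA copy number this chain represents in
#'   a pooled network (mean-field collapse of identical copies).
#' @param modulation optional function of time returning a value in
#'   \code{[0,1]} that multiplies the \eqn{\lambda_0 u} input term.
#' @param gene_id optional identifier carried through to trajectories.
#' @return object of class \code{rfmio_spec} with fields \code{n},
#'   \code{lambda}, \code{copy_weight}, \code{modulation}, \code{gene_id}.
#' @export
rfmio_spec <- function(lambda, copy_weight = 1, modulation = NULL,
                       gene_id = NA_character_) {
  lambda <- as.numeric(lambda)
  stopifnot(length(lambda) >= 2, all(is.finite(lambda)), all(lambda > 0),
            copy_weight >= 0,
            is.null(modulation) || is.function(modulation))
  structure(list(n = length(lambda) - 1L, lambda = lambda,
                 copy_weight = copy_weight, modulation = modulation,
                 gene_id = gene_id),
            class = "rfmio_spec")
}

#' @export
print.rfmio_spec <- function(x, ...) {
  cat(sprintf("RFMIO chain: n = %d sites, lambda in [%.4g, %.4g], copies %.4g\n",
              x$n, min(x$lambda), max(x$lambda), x$copy_weight))
  invisible(x)
}

#' Right-hand side of a single chain
#'
#' Flows are \eqn{h_i(x) = \lambda_i x_i (1 - x_{i+1})} with the boundary
#' conventions: the input flow is \eqn{\lambda_0 u (1 - x_1)} and the exit
#' flow \eqn{\lambda_n x_n} (i.e. \eqn{x_{n+1} \equiv 0}). The derivative at
#' site \eqn{i} is inflow minus outflow.
#'
#' @param x occupancy vector, length \code{spec$n}, inside \code{[0,1]}.
#' @param spec an \code{rfmio_spec}.
#' @param u nonnegative external input scaling the initiation flow.
#' @return derivative vector of length \code{n}.
#' @export
rfm_rhs <- function(x, spec, u = 1) {
  n <- spec$n
  if (length(x) != n) stop("state length does not match spec$n")
  stopifnot(u >= 0)
  lam <- spec$lambda
  # outflow of site i: lam[i+1] * x_i * (1 - x_{i+1}); x_{n+1} = 0
  out <- lam[-1] * x * (1 - c(x[-1], 0))
  inflow <- c(lam[1] * u * (1 - x[1]), out[-n])
  inflow - out
}

# Tridiagonal solve (Thomas algorithm): sub/diag/super diagonals a, b, c
# and right-hand side d; assumes the usual diagonal-dominance of the chain
# Jacobian in the unit cube.
thomas_solve <- function(a, b, c, d) {
  n <- length(b)
  if (n == 1L) return(d / b)
  cp <- numeric(n - 1L)
  dp <- numeric(n)
  cp[1] <- c[1] / b[1]
  dp[1] <- d[1] / b[1]
  for (i in 2:n) {
    m <- b[i] - a[i - 1L] * cp[i - 1L]
    if (i < n) cp[i] <- c[i] / m
    dp[i] <- (d[i] - a[i - 1L] * dp[i - 1L]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1L):1L) x[i] <- dp[i] - cp[i] * x[i + 1L]
  x
}

# Damped Newton (pseudo-transient continuation) for the steady balance
# equations of one chain: implicit-Euler steps (I/dt - J) delta = f with
# the pseudo-timestep dt grown as the residual falls, so the iteration is
# globally convergent for this cooperative system and reduces to Newton
# near the solution. The Jacobian is tridiagonal; steps that leave the
# open unit cube or inflate the residual shrink dt. Returns NULL when the
# iteration stalls (caller falls back to ODE relaxation).
chain_newton <- function(lambda, u, x0, tol, max_iter = 2000L) {
  n <- length(lambda) - 1L
  lam0u <- lambda[1] * u
  lam <- lambda[-1]                     # lambda_1 .. lambda_n
  rhs <- function(x) {
    out <- lam * x * (1 - c(x[-1], 0))
    c(lam0u * (1 - x[1]), out[-n]) - out
  }
  x <- x0
  f <- rhs(x)
  nf <- max(abs(f))
  dt <- 1 / max(lambda)
  for (iter in seq_len(max_iter)) {
    if (nf < tol) return(x)
    xn <- c(x[-1], 0)
    diag_ <- -c(lam0u, lam[-n] * x[-n]) - lam * (1 - xn)
    sub <- lam[-n] * (1 - x[-1])        # df_i/dx_{i-1}
    sup <- lam[-n] * x[-n]              # df_i/dx_{i+1}
    ok <- FALSE
    for (tries in 1:60) {
      delta <- thomas_solve(-sub, 1 / dt - diag_, -sup, f)
      xt <- x + delta
      if (all(is.finite(xt)) && all(xt > 0) && all(xt < 1)) {
        ft <- rhs(xt)
        nft <- max(abs(ft))
        if (nft < 2 * nf) { ok <- TRUE; break }
      }
      dt <- dt / 4
    }
    if (!ok) return(NULL)
    dt <- min(dt * min(max(nf / nft, 1.05), 10), 1e14)
    x <- xt; f <- ft; nf <- nft
  }
  NULL
}

#' Steady state of a single chain
#'
#' The chain admits a unique, globally asymptotically stable steady state in
#' the interior of the unit cube. The default solver is a damped Newton
#' iteration on the balance equations with a tridiagonal linear solve,
#' started from the cube centre (or \code{x0}), with an automatic fallback
#' to ODE relaxation if the iteration stalls; \code{method = "ode"} forces
#' the relaxation route (kept as an independent cross-check).
#'
#' @param spec an \code{rfmio_spec}.
#' @param u positive input.
#' @param method \code{"newton"} (default) or \code{"ode"}.
#' @param tol residual tolerance (max-norm of the RHS at the solution).
#' @param x0 initial occupancies (default all 0.5).
#' @return list with \code{e} (occupancies), \code{R} (translation rate
#'   \eqn{\lambda_n e_n}) and \code{rho} (mean density \eqn{\sum e_i / n}).
#' @examples
#' steady_state_chain(rfmio_spec(c(1, 1)), u = 1)  # e = 0.5, R = 0.5
#' @export
steady_state_chain <- function(spec, u = 1,
                               method = c("newton", "ode"),
                               tol = 1e-10, x0 = NULL) {
  method <- match.arg(method)
  stopifnot(u > 0)
  lam <- spec$lambda
  if (method == "newton") {
    n <- spec$n
    start <- if (is.null(x0)) rep(0.5, n) else pmin(pmax(x0, 1e-9), 1 - 1e-9)
    e <- chain_newton(lam, u, start, tol)
    if (is.null(e) && !is.null(x0))          # retry from the cube centre
      e <- chain_newton(lam, u, rep(0.5, n), tol)
    if (is.null(e)) {
      # continuation in u: the chain is easy to solve in the
      # initiation-limited regime; walk the input up with warm starts
      x <- rep(0.5, n)
      for (uk in u * c(1e-4, 1e-3, 1e-2, 0.05, 0.1, 0.25, 0.5, 0.75, 1)) {
        xk <- chain_newton(lam, uk, x, tol)
        if (is.null(xk)) { x <- NULL; break }
        x <- xk
      }
      e <- x
    }
    if (is.null(e))                          # ODE relaxation fallback
      return(steady_state_chain(spec, u, method = "ode", tol = tol))
  } else {
    n <- spec$n
    if (is.null(x0)) x0 <- rep(0.5, n)
    f <- function(t, y, p) list(rfm_rhs(y, spec, u))
    y <- x0
    for (k in 1:60) {
      sol <- deSolve::ode(y, c(0, 200 / min(lam)), f, NULL,
                          method = "lsoda", rtol = 1e-10, atol = 1e-12)
      y <- sol[nrow(sol), -1]
      if (max(abs(rfm_rhs(y, spec, u))) < 1e-10) break
    }
    if (max(abs(rfm_rhs(y, spec, u))) >= 1e-10)
      stop("ODE relaxation did not converge within the iteration budget")
    e <- unname(y)
  }
  list(e = e, R = lam[length(lam)] * e[length(e)], rho = mean(e))
}
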