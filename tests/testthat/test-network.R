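test_that("the weighted sum of all derivatives vanishes identically", {
  sys <- tiny_system(5, seed = 51, length_range = c(25L, 200L))
  pool <- pool_spec(sys$H0, c = sys$H0 / 10)
  set.seed(1)
  state <- network_state(lapply(sys$specs, function(s) stats::runif(s$n)),
                         z = sys$H0 / 3)
  d <- network_rhs(state, sys$specs, pool)
  w <- vapply(sys$specs, `[[`, 0, "copy_weight")
  total <- d$dz + sum(w * vapply(d$dx, sum, 0))
  expect_lt(abs(total) / max(abs(d$dz), 1), 1e-12)
})

test_that("an empty network with z = 200000 has H = 200000 and no binding at z = 0", {
  spec <- rfmio_spec(c(1, 1), copy_weight = 1)
  st <- network_state(list(0), z = 200000)
  expect_equal(total_ribosomes(st, list(spec)), 200000)
  # G(0) = 0: nothing binds, only chain outflow feeds the pool
  st0 <- network_state(list(0.4), z = 0)
  d <- network_rhs(st0, list(spec), pool_spec(10, c = 2))
  expect_equal(d$dx[[1]], -0.4)
  expect_equal(d$dz, 0.4)
  # moving ribosomes between pool and sites leaves H unchanged
  expect_equal(total_ribosomes(network_state(list(0.9), z = 199999.5),
                               list(spec)),
               total_ribosomes(network_state(list(0.4), z = 200000), list(spec)))
})

test_that("ribosome count is conserved along unforced trajectories", {
  sys <- tiny_system(5, seed = 51, length_range = c(25L, 200L))
  pool <- pool_spec(sys$H0, c = sys$H0 / 20)
  set.seed(2)
  st <- network_state(lapply(sys$specs, function(s) stats::runif(s$n, 0, 0.2)),
                      z = sys$H0 * 0.5)
  st$z <- sys$H0 - total_ribosomes(st, sys$specs) + st$z
  sol <- integrate_network(st, sys$specs, pool, times = seq(0, 1000, by = 5))
  w_site <- rep(vapply(sys$specs, `[[`, 0, "copy_weight"),
                vapply(sys$specs, `[[`, 0L, "n"))
  N <- length(w_site)
  H <- sol[, N + 2] + as.vector(sol[, 1 + seq_len(N), drop = FALSE] %*% w_site)
  expect_lt((max(H) - min(H)) / H[1], 1e-6)
})

test_that("hand-solved one-chain pool fixed point is reproduced", {
  # n = 1, lambda = (1, 1), G(z) = z, weight 1, H0 = 1:
  # z(1 - e) = e and z + e = H0  =>  e = (2 + H0 - sqrt((2 + H0)^2 - 4 H0))/2
  H0 <- 1
  spec <- rfmio_spec(c(1, 1), copy_weight = 1)
  pool <- pool_spec(H0, "linear", c = 1)
  st <- solve_network_steady(list(spec), pool)
  e_hand <- (2 + H0 - sqrt((2 + H0)^2 - 4 * H0)) / 2
  expect_close(st$x[[1]], e_hand, 1e-9)
  expect_close(st$z, H0 - e_hand, 1e-9)
})

test_that("network steady state is independent of the initial ribosome split", {
  sys <- tiny_system(4, seed = 52, length_range = c(25L, 120L))
  pool <- pool_spec(sys$H0, c = sys$H0 / 30)
  st <- solve_network_steady(sys$specs, pool)
  # relax the ODE from two very different splits of the same H0 and compare
  w <- vapply(sys$specs, `[[`, 0, "copy_weight")
  n <- vapply(sys$specs, `[[`, 0L, "n")
  for (frac in c(0.3, 0.95)) {
    fill <- sys$H0 * (1 - frac) / sum(w * n)  # uniform occupancy split
    expect_lt(fill, 1)
    st0 <- network_state(lapply(n, function(k) rep(fill, k)),
                         z = sys$H0 * frac)
    sol <- integrate_network(st0, sys$specs, pool,
                             times = c(0, 5000), rtol = 1e-10, atol = 1e-12)
    zT <- sol[nrow(sol), ncol(sol)]
    expect_close(zT, st$z, 1e-6 * sys$H0)
  }
})

test_that("mean-field collapse: k unit-weight copies equal one k-weight chain", {
  sys <- tiny_system(3, seed = 53, length_range = c(25L, 80L))
  base <- sys$specs[[1]]
  one <- rfmio_spec(base$lambda, copy_weight = 2)
  two <- list(rfmio_spec(base$lambda, copy_weight = 1),
              rfmio_spec(base$lambda, copy_weight = 1))
  H0 <- 20
  pool <- pool_spec(H0, c = 5)
  x0 <- rep(0.1, base$n)
  st1 <- network_state(list(x0), z = H0 - 2 * sum(x0))
  st2 <- network_state(list(x0, x0), z = H0 - 2 * sum(x0))
  t_out <- seq(0, 100, by = 1)
  s1 <- integrate_network(st1, list(one), pool, t_out,
                          rtol = 1e-10, atol = 1e-12)
  s2 <- integrate_network(st2, two, pool, t_out,
                          rtol = 1e-10, atol = 1e-12)
  expect_close(s1[, ncol(s1)], s2[, ncol(s2)], 1e-8 * H0)  # z trajectories
  expect_close(s1[, 2], s2[, 2], 1e-8)                      # first site
})

test_that("raising one gene's copy number lowers the free pool and no rival's output", {
  sys <- tiny_system(5, seed = 54, length_range = c(25L, 150L))
  pool <- pool_spec(sys$H0, c = sys$H0 / 20)
  st <- solve_network_steady(sys$specs, pool)
  R0 <- attr(st, "R")
  specs2 <- sys$specs
  specs2[[2]]$copy_weight <- specs2[[2]]$copy_weight * 3
  st2 <- solve_network_steady(specs2, pool)
  expect_lt(st2$z, st$z)
  expect_true(all(attr(st2, "R")[-2] <= R0[-2] + 1e-10))
})

test_that("pool calibration hits the requested free-pool percentage", {
  sys <- tiny_system(6, seed = 55, length_range = c(25L, 1000L))
  for (target in c(40, 60)) {
    pool <- calibrate_pool(sys$specs, sys$H0, target)
    st <- solve_network_steady(sys$specs, pool)
    expect_lt(abs(100 * st$z / sys$H0 - target), 0.1)
  }
  # larger scale c leaves more ribosomes free (monotonicity)
  zb <- vapply(sys$H0 * c(0.5, 1, 2, 4), function(cc) {
    st <- solve_network_steady(sys$specs, pool_spec(sys$H0, c = cc))
    100 * st$z / sys$H0
  }, 0)
  expect_true(all(diff(zb) > 0))
  # below the saturated-pool floor: infeasible, reported with the bracket
  expect_error(calibrate_pool(sys$specs, sys$H0, 1), "achievable")
})
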