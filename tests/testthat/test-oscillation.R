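test_that("forced mRNA level follows the sinusoid", {
  spec <- oscillation_spec("g1", L_h = 12000, A = 0.5, T = 16)
  expect_equal(mrna_level(0, spec), 12000)
  expect_equal(mrna_level(4, spec), 18000)     # t = T/4, peak
  expect_equal(mrna_level(12, spec), 6000)     # t = 3T/4, trough
  flat <- oscillation_spec("g1", L_h = 500, A = 0, T = 16)
  expect_true(all(mrna_level(seq(0, 32, by = 0.5), flat) == 500))
})

test_that("the modulated two-chain split realizes the instantaneous level exactly", {
  base <- rfmio_spec(c(0.4, 0.6, 0.6, 0.5), gene_id = "rep")
  grp <- build_modulated_group(base, L_h = 12000, A = 0.5, T = 16)
  expect_length(grp, 2)
  expect_equal(grp[[1]]$copy_weight, 6000)     # beta1 = L_h (1 - A)
  expect_equal(grp[[2]]$copy_weight, 12000)    # beta2 - beta1 = 2 A L_h
  expect_equal(grp[[1]]$lambda, base$lambda)
  expect_equal(grp[[2]]$lambda, base$lambda)
  osc <- oscillation_spec("rep", 12000, 0.5, 16)
  tgrid <- seq(0, 32, length.out = 101)
  eff <- grp[[1]]$copy_weight +
    grp[[2]]$copy_weight * vapply(tgrid, grp[[2]]$modulation, 0)
  expect_close(eff, mrna_level(tgrid, osc), 1e-9)
  # A = 0 collapses to a single constant chain at the nominal level
  flat <- build_modulated_group(base, L_h = 500, A = 0)
  expect_length(flat, 1)
  expect_equal(flat[[1]]$copy_weight, 500)
  expect_null(flat[[1]]$modulation)
})

test_that("unforced simulation entrains immediately with zero amplitudes", {
  sys <- tiny_system(4, seed = 61, length_range = c(25L, 120L))
  pool <- calibrate_pool(sys$specs, sys$H0, 30)
  traj <- simulate_entrained(sys$specs, pool, T = 16,
                             samples_per_period = 32)
  expect_lte(traj$periods, 2)
  st <- summarize_amplitudes(traj)
  expect_lt(st$z_a, 1e-6)
  expect_lt(st$Rbar_a, 1e-4)
  expect_close(st$zbar, 30, 0.1)
})

test_that("forced network entrains to the forcing period with dominant DFT bin 1/T", {
  sys <- tiny_system(6, seed = 62, length_range = c(25L, 300L))
  osc_gene <- sys$genome$genes[[1]]
  specs <- c(build_modulated_group(sys$specs[[1]], osc_gene$mrna_level,
                                   A = 0.5, T = 16),
             sys$specs[-1])
  pool <- calibrate_pool(specs, sys$H0, 30)
  traj <- simulate_entrained(specs, pool, T = 16)
  expect_lt(traj$residual, 1e-6)
  # dominant discrete-Fourier frequency of z equals the forcing frequency
  zc <- traj$z[-length(traj$z)]
  sp <- Mod(stats::fft(zc - mean(zc)))
  expect_equal(which.max(sp[2:(length(zc) %/% 2)]), 1L)
  # conservation holds under forcing
  expect_lt(diff(range(
    traj$z + vapply(seq_along(traj$time), function(i) {
      sum(traj$copy_weights * traj$rho[i, ] *
            vapply(specs, `[[`, 0L, "n"))
    }, 0))) / sys$H0, 1e-6)
  # the period-map residual decreases monotonically in the tail
  tail_res <- utils::tail(traj$residuals, 5)
  expect_true(all(diff(tail_res) < 0))
})

test_that("doubling the forcing period entrains at the doubled period", {
  sys <- tiny_system(4, seed = 63, length_range = c(25L, 1000L))
  g1 <- sys$genome$genes[[1]]
  mk <- function(T_) c(build_modulated_group(sys$specs[[1]], g1$mrna_level,
                                             A = 0.4, T = T_),
                       sys$specs[-1])
  specs16 <- mk(16); specs32 <- mk(32)
  pool <- calibrate_pool(specs16, sys$H0, 30)
  t16 <- simulate_entrained(specs16, pool, T = 16, tol = 1e-8)
  t32 <- simulate_entrained(specs32, pool, T = 32, tol = 1e-8)
  # both entrain, each at its own forcing period (dominant DFT bin 1)
  dominant <- function(z) {
    z <- z[-length(z)]
    which.max(Mod(stats::fft(z - mean(z)))[2:(length(z) %/% 2)])
  }
  expect_equal(dominant(t16$z), 1L)
  expect_equal(dominant(t32$z), 1L)
  s16 <- summarize_amplitudes(t16)
  s32 <- summarize_amplitudes(t32)
  # the cell state is the same up to the period-mean shift of rectification
  expect_close(s16$zbar, s32$zbar, 2)
  # slower forcing gives the chains more time to follow: amplitude grows
  expect_gt(s32$z_a, s16$z_a)
})
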