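test_that("rebinding generator is exact at zero noise and seed-reproducible", {
  rt <- ngb_rates("cace")
  cond <- condition(co_atm = 1)
  tr0 <- gen_rebinding(rt$rates, cond, n_points = 46, noise = noise_model(0, 1))
  sim <- simulate_scheme(rt$rates, cond, tr0$times)
  expect_equal(tr0$signal, sim$signal, tolerance = 1e-12)

  trA <- gen_rebinding(rt$rates, cond, noise = noise_model(0.01, 7))
  trB <- gen_rebinding(rt$rates, cond, noise = noise_model(0.01, 7))
  expect_identical(trA$signal, trB$signal)
  trC <- gen_rebinding(rt$rates, cond, noise = noise_model(0.01, 8))
  expect_false(identical(trA$signal, trC$signal))
})

test_that("lower CO pressure slows the second-order phase", {
  rt <- ngb_rates("cace")
  tr1 <- gen_rebinding(rt$rates, condition(co_atm = 1), noise = noise_model(0, 1))
  tr01 <- gen_rebinding(rt$rates, condition(co_atm = 0.1), noise = noise_model(0, 1))
  # half-recovery times of the unbound fraction from the expm oracle
  half_time <- function(cond) {
    tt <- log_times(1e-9, 10, 20)
    P <- oracle_states(rt$rates, cond, tt)
    tt[which(P[, "B0"] >= 0.5)[1]]
  }
  t_half_1 <- half_time(condition(co_atm = 1))
  t_half_01 <- half_time(condition(co_atm = 0.1))
  expect_gt(t_half_01, t_half_1)
  # and the generated traces show the same ordering
  i1 <- which(tr1$signal <= 0.5)[1]
  i01 <- which(tr01$signal <= 0.5)[1]
  expect_gt(tr01$times[i01], tr1$times[i1])
})

test_that("temperature series regenerates Eyring parameters round-trip", {
  nm <- names(ngb_rates("cace")$rates)
  dh <- stats::setNames(rep(8, 15), nm)
  dh["k_m1"] <- 10
  temps <- c(278.15, 283.15, 288.15, 293.15)
  ser <- gen_temperature_series(dh, temps = temps, noise = noise_model(0, 1),
                                n_points = 10)
  expect_length(ser, 4)
  k_m1 <- vapply(ser, function(s) s$rates[["k_m1"]], 0)
  fit <- eyring_fit(temps, k_m1)
  expect_equal(fit$delta_h_kcal, 10, tolerance = 1e-6)
  expect_equal(fit$delta_s_kcal_per_K, 0, tolerance = 1e-9)

  # flat activation enthalpy (dH = 0, dS tuned to a fixed k) gives
  # identical kinetics at every temperature once noise is off
  dh0 <- stats::setNames(rep(0, 15), nm)
  ser0 <- gen_temperature_series(dh0, temps = temps[1:2],
                                 noise = noise_model(0, 1), n_points = 15)
  r1 <- as.numeric(ser0[[1]]$rates) / ser0[[1]]$temperature_K
  r2 <- as.numeric(ser0[[2]]$rates) / ser0[[2]]$temperature_K
  expect_equal(r1, r2, tolerance = 1e-12)   # k/T constant when dH = 0

  expect_error(gen_temperature_series(dh, temps = numeric(0)), "empty")
  expect_error(gen_temperature_series(dh, temps = c(200, 293)), "273-310")
})

test_that("relaxation generator produces the declared mixture", {
  tr <- gen_relaxation(cbind(1, 0.05), duration = 100, n_points = 50, sigma = 0)
  expect_equal(tr$signal, exp(-0.05 * tr$times), tolerance = 1e-12)
  tr2 <- gen_relaxation(cbind(c(0.96, 0.04), c(0.1, 1)), duration = 50,
                        n_points = 50, sigma = 0)
  expect_equal(tr2$signal, 0.96 * exp(-0.1 * tr2$times) + 0.04 * exp(-tr2$times),
               tolerance = 1e-12)
  # minor fraction below the 5% heterogeneity threshold by construction
  expect_lt(0.04 / (0.96 + 0.04), 0.05)
  expect_error(gen_relaxation(cbind(-1, 0.1), 10), "> 0")
})

test_that("toy trajectory jitter and template behave as documented", {
  f0 <- gen_toy_trajectory(3, jitter = 0)
  expect_identical(f0$frames[[1]], f0$frames[[3]])
  f1 <- gen_toy_trajectory(3, jitter = 0.2, seed = 1)
  expect_false(identical(f1$frames[[1]], f1$frames[[2]]))
  expect_equal(f1$n_atoms, f0$n_atoms)
  expect_error(gen_toy_trajectory(0), ">= 1")
})
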