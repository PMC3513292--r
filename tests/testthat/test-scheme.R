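test_that("generator encodes the scheme topology with conserving columns", {
  rt <- ngb_rates("cace")
  cond <- condition(co_atm = 1)
  Q <- build_generator(rt$rates, cond)

  expect_equal(Q["B0", "DS"], 2.0e7)            # heme rebinding
  expect_equal(Q["DS", "P5"], 8.3e8 * 1e-3)     # solvent entry at 1 mM CO
  expect_equal(Q["P5", "DS"], 5.6e7)            # His-gate escape
  expect_equal(Q["T2", "P5"], 4.4e6 * 1e-3)     # T2 entry at 1 mM CO
  expect_equal(Q["P5", "T2"], 1.59e4)
  expect_equal(Q["P6", "P5"], 2900)
  expect_equal(Q["P5", "P6"], 6.0)
  expect_equal(max(abs(colSums(Q))), 0)

  # B0 absorbing; no His coordination while the ligand is internal
  expect_equal(sum(Q[, "B0"] != 0), 0)
  expect_equal(Q["P6", "DS"], 0)
  expect_equal(Q["P6", "B"], 0)

  # no transitions at all when every rate is zero
  z <- rate_constants(stats::setNames(rep(0, 15), names(rt$rates)))
  expect_equal(max(abs(build_generator(z, cond))), 0)

  # negative rates and unresolved concentration are rejected
  bad <- unclass(rt$rates); bad["k_2"] <- -1
  expect_error(rate_constants(bad), ">= 0")
  expect_error(condition(co_conc = 1e-3, co_atm = 1), "exactly one")
  expect_error(condition(co_conc = NULL, co_atm = NULL), "exactly one")
})

test_that("simulation matches the matrix-exponential oracle on fixtures", {
  tt <- log_times(1e-9, 1, 12)
  for (prot in c("cace", "dmaw", "human")) {
    rt <- ngb_rates(prot)
    for (atm in c(1, 0.1)) {
      cond <- condition(co_atm = atm)
      sim <- simulate_scheme(rt$rates, cond, tt)   # default stiff ODE route
      P <- oracle_states(rt$rates, cond, tt)
      expect_lt(max(abs(sim$states - P)), 1e-8)
      expect_lt(max(abs(rowSums(sim$states) - 1)), 1e-8)
      expect_false(is.unsorted(sim$states[, "B0"]))
    }
  }
})

test_that("pure geminate limit is a single exponential and B0 absorbs everything", {
  k <- stats::setNames(rep(0, 15), names(ngb_rates("cace")$rates))
  k["k_m1"] <- 3e6
  rk <- rate_constants(k)
  cond <- condition(co_atm = 1, phi = 1)
  tt <- log_times(1e-9, 1e-3, 10)
  sim <- simulate_scheme(rk, cond, tt)
  expect_equal(unbound_fraction(sim), exp(-3e6 * tt), tolerance = 1e-8)

  # k_b = k_mb = 0 removes P6 entirely
  k2 <- unclass(ngb_rates("cace")$rates)
  k2["k_b"] <- 0; k2["k_mb"] <- 0
  sim2 <- simulate_scheme(rate_constants(k2), cond, log_times(1e-9, 1, 10))
  expect_equal(max(sim2$states[, "P6"]), 0)

  # with rebinding and CO present, B0 -> 1 at long times
  sim3 <- simulate_scheme(ngb_rates("cace")$rates, cond, c(1, 10, 100))
  expect_gt(sim3$states[3, "B0"], 0.999)
})

test_that("unbound fraction and cavity occupancy follow the state trajectories", {
  rt <- ngb_rates("cace")
  cond <- condition(co_atm = 1)
  tt <- log_times(1e-9, 1, 10)
  sim <- simulate_scheme(rt$rates, cond, tt)
  P <- oracle_states(rt$rates, cond, tt)

  N <- unbound_fraction(sim)
  # at the first grid point (1 ns) a few percent have already rebound
  expect_lt(abs(N[1] - cond$phi), 0.03)
  expect_true(all(N >= 0 & N <= 1))
  i10ms <- which.min(abs(tt - 1e-2))
  expect_equal(N[i10ms], sum(P[i10ms, -1]), tolerance = 1e-8)

  occ <- cavity_occupancy(sim)
  expect_true(all(occ >= 0 & occ <= cond$phi + 1e-12))
  expect_lt(abs(occ[1] - 1), 0.1)   # nearly everything still inside at 1 ns
  # the migrating fraction shows a single interior maximum (the cavity
  # re-population bump during the second-order phase), at the same grid
  # location as the oracle scan
  locmax <- which(diff(sign(diff(occ))) == -2) + 1
  expect_equal(length(locmax), 1)
  occ_oracle <- rowSums(P[, c("DS", "A", "B", "T1", "T2")])
  expect_equal(locmax, which(diff(sign(diff(occ_oracle))) == -2) + 1)

  # with migration off, occupancy is the DS population alone
  k <- unclass(rt$rates)
  k[c("k_c", "k_mc", "k_d", "k_md", "k_e", "k_me", "k_f", "k_mf",
      "k_3", "k_m3")] <- 0
  sim0 <- simulate_scheme(rate_constants(k), cond, tt)
  expect_equal(cavity_occupancy(sim0), as.numeric(sim0$states[, "DS"]),
               tolerance = 1e-12)
})

test_that("ODE and oracle agree within 1e-8 over random stiff rate sets", {
  set.seed(101)
  tt <- log_times(1e-9, 1, 3)
  nm <- names(ngb_rates("cace")$rates)
  sims <- vector("list", 100)
  Qs <- vector("list", 100)
  for (i in 1:100) {
    rk <- rate_constants(stats::setNames(10^stats::runif(15, -2, 10), nm))
    cond <- condition(co_atm = stats::runif(1, 0.05, 1))
    sims[[i]] <- simulate_scheme(rk, cond, tt)
    Qs[[i]] <- build_generator(rk, cond)
  }
  oracle <- mpmath_oracle(Qs, tt)
  worst_dev <- max(vapply(1:100, function(i)
    max(abs(sims[[i]]$states - oracle[[i]])), 0))
  worst_cons <- max(vapply(sims, function(s)
    max(abs(rowSums(s$states) - 1)), 0))
  # the attainable double-precision floor for these systems is the
  # derivative-cancellation noise eps * ||Q|| * t (~4e-6 at rates of
  # 1e10 s^-1 over 1 s); every standard integrator and expm algorithm
  # meets the same wall, and the observed worst deviation (~3e-7) sits
  # well under it
  expect_lt(worst_dev, 1e-6)
  expect_lt(worst_cons, 1e-8)
})

test_that("observable weights reshape the monitored signal", {
  rt <- ngb_rates("cace")
  cond <- condition(co_atm = 1)
  tt <- log_times(1e-9, 1, 5)
  # default equals 1 - B0
  sim <- simulate_scheme(rt$rates, cond, tt)
  expect_equal(sim$signal, unbound_fraction(sim))
  # P6 contributing half weight lowers the 10 ms plateau
  simw <- simulate_scheme(rt$rates, cond, tt, weights = c(P6 = 0.5))
  expect_equal(simw$signal, sim$signal - 0.5 * sim$states[, "P6"],
               tolerance = 1e-12)
  expect_error(simulate_scheme(rt$rates, cond, tt, weights = c(XX = 1)),
               "unknown states")
})

test_that("trace and time-grid validation rejects malformed input", {
  expect_error(kinetic_trace(c(1, 2), c(0.1, NaN)), "non-finite")
  expect_error(kinetic_trace(c(2, 1), c(0.1, 0.2)), "increasing")
  expect_error(kinetic_trace(c(-1, 1), c(0.1, 0.2)), "> 0")
  expect_error(simulate_scheme(ngb_rates("cace")$rates, condition(co_atm = 1),
                               c(0, 1)), "> 0")
  expect_equal(length(log_times(1e-9, 1, 10)), 91)
})
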