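test_that("log-time resampling is idempotent and counts bins correctly", {
  rt <- ngb_rates("cace")
  cond <- condition(co_atm = 1)
  # trace already on a 10-per-decade grid passes through unchanged
  tr <- gen_rebinding(rt$rates, cond, n_points = 91, noise = noise_model(0, 1))
  rs <- resample_log_time(tr, 10)
  expect_equal(rs$times, tr$times, tolerance = 1e-12)
  expect_equal(rs$signal, tr$signal, tolerance = 1e-12)

  # dense sampling across 9 decades fills every bin: 9 x 10 + 1 nodes
  dense <- gen_rebinding(rt$rates, cond, n_points = 2000, noise = noise_model(0, 1))
  rs2 <- resample_log_time(dense, 10)
  expect_length(rs2$times, 91)
  expect_false(is.unsorted(rs2$times, strictly = TRUE))

  # negative or zero times never reach the resampler
  expect_error(kinetic_trace(c(-1e-9, 1e-6), c(1, 0.5)), "> 0")
})

test_that("one-parameter fits recover the generating rate almost exactly", {
  nm <- names(ngb_rates("cace")$rates)
  k <- stats::setNames(rep(0, 15), nm)
  k["k_m1"] <- 3.3e6
  rk <- rate_constants(k)
  cond <- condition(co_atm = 1)
  # 51 log-spaced points = exactly the 10-per-decade objective grid over
  # five decades, so resampling is the identity and recovery is exact
  tr <- gen_rebinding(rk, cond, n_points = 51, noise = noise_model(0, 1),
                      t_max = 1e-4, method = "eigen")
  spec <- fit_spec(free = "k_m1")
  fit <- fit_traces(tr, spec, n_starts = 5, seed = 2)
  expect_lt(abs(10^fit$log10_estimates[["k_m1"]] / 3.3e6 - 1), 1e-3)
  expect_true(fit$converged)

  # fixed seed gives a bit-identical result
  fit2 <- fit_traces(tr, spec, n_starts = 5, seed = 2)
  expect_identical(fit$log10_estimates, fit2$log10_estimates)
  expect_identical(fit$ssr, fit2$ssr)

  # multi-start best-of never loses to the single-start fit
  fit1 <- fit_traces(tr, spec, n_starts = 1, seed = 2)
  expect_lte(fit$ssr, fit1$ssr + 1e-15)

  # noiseless data: the correct model is reproduced to numerical depth
  res <- fit$intermediates[[1]]$signal - fit$traces[[1]]$signal
  expect_lt(sqrt(mean(res^2)), 1e-6)

  # with the correctly specified model fitted to noisy data the residuals
  # are structureless: Wald-Wolfowitz runs test at alpha = 0.01
  trn <- gen_rebinding(rk, cond, n_points = 51, noise = noise_model(0.005, 9),
                       t_max = 1e-4, method = "eigen")
  fitn <- fit_traces(trn, spec, n_starts = 5, seed = 2)
  resn <- fitn$intermediates[[1]]$signal - fitn$traces[[1]]$signal
  expect_lt(abs(runs_test_z(resn)), stats::qnorm(1 - 0.01 / 2))
})

test_that("core rates of the reduced scheme are recovered from noisy pairs", {
  nm <- names(ngb_rates("cace")$rates)
  k <- unclass(ngb_rates("cace")$rates)
  k[c("k_c", "k_mc", "k_d", "k_md", "k_e", "k_me", "k_f", "k_mf",
      "k_3", "k_m3")] <- 0
  rk <- rate_constants(k)
  traces <- list(
    gen_rebinding(rk, condition(co_atm = 1), noise = noise_model(0.005, 31),
                  method = "eigen"),
    gen_rebinding(rk, condition(co_atm = 0.1), noise = noise_model(0.005, 32),
                  method = "eigen"))
  spec <- fit_spec(free = c("k_m1", "k_2", "k_m2", "k_b", "k_mb"),
                   init = rate_constants(replace(k, k == 0, 1e-3)))
  fit <- fit_traces(traces, spec, n_starts = 20, seed = 3,
                    strategy = "staged", n_hops = 10)
  err <- fit$log10_estimates[c("k_m1", "k_2", "k_m2", "k_b", "k_mb")] -
    log10(k[c("k_m1", "k_2", "k_m2", "k_b", "k_mb")])
  expect_lt(max(abs(err)), 0.15)
})

test_that("input contracts and identifiability diagnostics", {
  rt <- ngb_rates("cace")
  tr <- gen_rebinding(rt$rates, condition(co_atm = 1), n_points = 30,
                      noise = noise_model(0, 1))
  # NaN in a trace is refused at construction
  expect_error(kinetic_trace(tr$times, replace(tr$signal, 3, NaN)),
               "non-finite")
  # traces at different temperatures cannot share parameters
  tr2 <- gen_rebinding(rt$rates, condition(temperature_K = 283.15, co_atm = 1),
                       n_points = 30, noise = noise_model(0, 1))
  expect_error(fit_traces(list(tr, tr2), fit_spec()), "temperature")
  # single trace with all 15 rates free warns about unidentifiability
  w <- capture_warnings(
    fit_traces(tr, fit_spec(), strategy = "local", maxiter = 5))
  expect_true(any(grepl("unidentifiable", w)))
})

test_that("objective profiles separate identifiable from flat directions", {
  nm <- names(ngb_rates("cace")$rates)
  k <- stats::setNames(rep(0, 15), nm)
  k["k_m1"] <- 1e6
  k["k_me"] <- 1e3        # irrelevant: with k_e = 0, T1 is never populated
  rk <- rate_constants(k)
  tr <- gen_rebinding(rk, condition(co_atm = 1), n_points = 51,
                      noise = noise_model(0.002, 5), t_max = 1e-4,
                      method = "eigen")
  spec <- fit_spec(free = c("k_m1", "k_me"), init = rk)
  fit <- suppressWarnings(fit_traces(tr, spec, strategy = "local"))

  pr <- suppressWarnings(
    profile_identifiability(fit, "k_m1", half_width = 0.3, n = 7))
  expect_true(pr$identifiable)
  expect_equal(min(pr$profile$objective), fit$ssr, tolerance = 1e-6)
  imin <- which.min(pr$profile$objective)
  expect_equal(pr$profile$log10_value[imin], fit$log10_estimates[["k_m1"]],
               tolerance = 0.06)

  pr2 <- suppressWarnings(
    profile_identifiability(fit, "k_me", half_width = 0.5, n = 5))
  expect_false(pr2$identifiable)

  expect_error(profile_identifiability(fit, "k_b"), "not a free parameter")
})
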