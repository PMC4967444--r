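test_that("forward model limiting cases: no exchange and pure plasma term", {
  tt <- seq(0.5, 5, by = 0.5)  # minutes
  a <- pop_aif_std

  none <- extended_tofts_forward(tofts_params(0, 0.3, 0), a, tt)
  expect_true(all(none$ct == 0))

  plasma <- extended_tofts_forward(tofts_params(0, 0.3, 0.05), a, tt)
  cp_at <- approx(a$times, a$cp, xout = tt * 60)$y
  expect_equal(plasma$ct, 0.05 * cp_at, tolerance = 1e-12)
})

test_that("trapezoidal convolution matches the boxcar closed form to 1e-4", {
  a <- boxcar_aif(T_s = 300, dt = 0.1)
  tt <- seq(0.1, 5, by = 0.1)  # minutes, all <= 300 s
  for (p in list(c(0.05, 0.2), c(0.12, 0.3), c(0.3, 0.6))) {
    cc <- extended_tofts_forward(tofts_params(p[1], p[2], 0), a, tt)
    closed <- p[2] * (1 - exp(-(p[1] / p[2]) * tt))
    expect_lt(max(abs(cc$ct - closed)), 1e-4)
  }
})

test_that("recursive convolution equals the direct trapezoidal oracle", {
  a <- pop_aif_std
  tt_min <- protocol_frame_times(std_protocol, "minutes")
  p <- tofts_params(0.08, 0.25, 0.03)
  cc <- extended_tofts_forward(p, a, tt_min)
  oracle <- oracle_tofts_ct(p$ktrans, p$ve, p$vp, a$times, a$cp)
  oracle_at <- approx(a$times, oracle, xout = tt_min * 60)$y
  expect_equal(cc$ct, oracle_at, tolerance = 1e-10)
})

test_that("early-time concentration is non-decreasing in Ktrans", {
  a <- pop_aif_std
  t_probe <- (protocol_bolus_delay(std_protocol) + 60) / 60  # 1 min post bolus
  kt_grid <- seq(0.01, 0.5, length.out = 12)
  ct <- vapply(kt_grid, function(k)
    extended_tofts_forward(tofts_params(k, 0.3, 0.02), a, t_probe)$ct, numeric(1))
  expect_true(all(diff(ct) >= 0))
})

test_that("requested times outside the AIF support are rejected", {
  a <- pop_aif_std
  expect_error(extended_tofts_forward(tofts_params(0.05, 0.3), a, c(1, 60)),
               "outside the AIF")
})

test_that("parameter invariants are validated", {
  expect_error(tofts_params(-0.1, 0.3), "ktrans")
  expect_error(tofts_params(0.1, 0), "ve")
  expect_error(tofts_params(0.1, 1.2), "ve")
  expect_error(tofts_params(0.1, 0.7, 0.5), "exceed 1")
})

test_that("noiseless round trip recovers the generating parameters within 1%", {
  truth <- tofts_params(0.045, 0.31, 0.02)
  ser <- simulate_signal_curve(truth, pop_aif_std, std_protocol,
                               s0 = 100, gain = 5, noise_sd = 0)
  s0 <- baseline_signal(ser)
  fit <- fit_extended_tofts(ser, s0, pop_aif_std, std_protocol, gain = 5)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$ktrans - truth$ktrans) / truth$ktrans, 0.01)
  expect_lt(abs(fit$params$ve - truth$ve) / truth$ve, 0.01)
})

test_that("fitting is deterministic and flags unusable series", {
  truth <- tofts_params(0.08, 0.4, 0.01)
  ser <- simulate_signal_curve(truth, pop_aif_std, std_protocol, noise_sd = 1.5, seed = 9)
  s0 <- baseline_signal(ser)
  f1 <- fit_extended_tofts(ser, s0, pop_aif_std, std_protocol)
  f2 <- fit_extended_tofts(ser, s0, pop_aif_std, std_protocol)
  expect_identical(f1, f2)

  flat <- fit_extended_tofts(rep(100, 18), 100, pop_aif_std, std_protocol)
  expect_lt(flat$params$ktrans, 1e-4)

  bad <- fit_extended_tofts(rep(0, 18), 100, pop_aif_std, std_protocol)
  expect_true(bad$error)
  expect_false(bad$converged)
  expect_equal(bad$params$ktrans, 0)

  nonfinite <- fit_extended_tofts(c(rep(100, 17), NaN), 100, pop_aif_std, std_protocol)
  expect_true(nonfinite$error)
})

test_that("median relative recovery error over random noiseless voxels is below 1%", {
  set.seed(1203)
  n <- 200
  kt <- runif(n, 0.01, 0.2)
  ve <- runif(n, 0.1, 0.6)
  vp <- runif(n, 0, 0.1)
  err_kt <- err_ve <- numeric(n)
  for (i in seq_len(n)) {
    tr <- tofts_params(kt[i], ve[i], vp[i])
    ser <- simulate_signal_curve(tr, pop_aif_std, std_protocol, noise_sd = 0)
    f <- fit_extended_tofts(ser, baseline_signal(ser), pop_aif_std, std_protocol)
    err_kt[i] <- abs(f$params$ktrans - kt[i]) / kt[i]
    err_ve[i] <- abs(f$params$ve - ve[i]) / ve[i]
  }
  expect_lt(median(err_kt), 0.01)
  expect_lt(median(err_ve), 0.01)
})

test_that("Ktrans error grows with signal noise (three-level ladder)", {
  truth <- tofts_params(0.045, 0.31, 0.02)
  noise_levels <- c(0.5, 3, 12)
  med_err <- vapply(noise_levels, function(ns) {
    errs <- vapply(1:30, function(i) {
      ser <- simulate_signal_curve(truth, pop_aif_std, std_protocol,
                                   noise_sd = ns, seed = 7000 + i)
      f <- fit_extended_tofts(ser, baseline_signal(ser), pop_aif_std, std_protocol)
      abs(f$params$ktrans - truth$ktrans)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) > 0))
})
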