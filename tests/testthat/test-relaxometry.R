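char_trs <- round(exp(seq(log(136), log(5000), length.out = 13)))

test_that("T1 is recovered exactly from noiseless recovery curves", {
  t1p <- relax_params("t1_satrec", 1, t1 = 282.1)
  s <- simulate_relaxation_series("saturation_recovery", t1p, char_trs)
  ft <- fit_t1(s$time, s$signal)
  expect_equal(ft$estimates[["T1"]], 282.1, tolerance = 1e-3)
  expect_equal(ft$estimates[["A"]], 1, tolerance = 1e-4)
})

test_that("fully saturated recovery is flagged unidentifiable", {
  t1p <- relax_params("t1_satrec", 2, t1 = 3)
  trs <- c(500, 1000, 2000, 4000)
  s <- simulate_relaxation_series("saturation_recovery", t1p, trs, 1e-4,
                                  seed = 4)
  ft <- fit_t1(s$time, s$signal)
  expect_true("t1_unidentifiable" %in% ft$flags)
  expect_equal(ft$estimates[["A"]], mean(s$signal), tolerance = 1e-6)
  expect_error(fit_t1(trs, rep(2, 4)), "identifiable")
  expect_error(fit_t1(c(1, 1, 1), c(1, 2, 3)), "distinct")
})

test_that("noiseless bi-exponential decays are recovered exactly", {
  p <- relax_ref$t2_bi$serum_pt
  te <- (1:32) * 3.2
  s <- simulate_relaxation_series("echo_decay", bi_params(p), te)
  ft <- fit_decay(s$time, s$signal, "bi")
  expect_equal(ft$estimates[["beta"]], p[["beta"]], tolerance = 1e-6)
  expect_equal(ft$estimates[["T2a"]], p[["t2a"]], tolerance = 1e-5)
  expect_equal(ft$estimates[["T2b"]], p[["t2b"]], tolerance = 1e-5)
  expect_lte(ft$estimates[["T2a"]], ft$estimates[["T2b"]])
})

test_that("the bi-exponential fit never loses to the nested mono fit", {
  te <- (1:24) * 4
  for (s in 1:8) {
    df <- simulate_relaxation_series("echo_decay",
                                     relax_params("mono_exp", 1, t2 = 30),
                                     te, 0.02, seed = s)
    fm <- fit_decay(df$time, df$signal, "mono")
    fb <- fit_decay(df$time, df$signal, "bi")
    expect_lte(fb$rss, fm$rss * (1 + 1e-10))
  }
})

test_that("likelihood ratio test reproduces the closed-form chi-square tail", {
  stub <- function(rss, n) structure(list(rss = rss, n_points = n),
                                     class = "f19_fit")
  eq <- likelihood_ratio_test(stub(3.3, 50), stub(3.3, 50))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_equal(eq$preferred_model, "mono")
  lr <- likelihood_ratio_test(stub(1.2, 50), stub(1.0, 50))
  expect_equal(lr$statistic, 50 * log(1.2), tolerance = 1e-12)
  # chi-square_2 survival has the closed form exp(-x/2)
  expect_equal(lr$p_value, exp(-50 * log(1.2) / 2), tolerance = 1e-12)
  expect_equal(lr$p_value, 0.0104826, tolerance = 1e-6)
  expect_equal(lr$preferred_model, "bi")
  expect_error(likelihood_ratio_test(stub(1, 50), stub(1, 49)), "same")
})

test_that("apparent T2 matches an independent bisection oracle", {
  cases <- list(c(0.405, 8.0, 21.7), c(0.880, 4.7, 12.9),
                c(0.425, 0.336, 1.83), c(0.3, 50, 400))
  for (cs in cases) {
    p <- relax_params("bi_exp", 1, beta = cs[1], t2a = cs[2], t2b = cs[3])
    expect_equal(apparent_t2(p), bisect_apparent_t2(cs[1], cs[2], cs[3]),
                 tolerance = 1e-8)
  }
  expect_equal(apparent_t2(relax_params("bi_exp", 1, beta = 1, t2a = 7,
                                        t2b = 99)), 7, tolerance = 1e-9)
  expect_equal(apparent_t2(relax_params("bi_exp", 1, beta = 0.5, t2a = 10,
                                        t2b = 10)), 10, tolerance = 1e-9)
})

test_that("apparent T2 always lies between the two time constants", {
  for (beta in seq(0, 1, by = 0.1)) {
    p <- relax_params("bi_exp", 1, beta = beta, t2a = 3, t2b = 40)
    tt <- apparent_t2(p)
    expect_gte(tt, 3); expect_lte(tt, 40)
  }
})

test_that("Monte-Carlo apparent T2 collapses onto the root as V_p -> 0", {
  p <- relax_ref$t2_bi$serum_pt
  root <- apparent_t2(bi_params(p))
  fit_stub <- list(estimates = c(A = 1, beta = p[["beta"]], T2a = p[["t2a"]],
                                 T2b = p[["t2b"]]),
                   covariance = diag(c(1e-12, 1e-12, 1e-10, 1e-10)))
  dimnames(fit_stub$covariance) <- list(names(fit_stub$estimates),
                                        names(fit_stub$estimates))
  mc <- apparent_t2_mc(fit_stub, n_samples = 2e4, seed = 5)
  expect_equal(mc$mean, root, tolerance = 1e-4)
  expect_lt(mc$sd, 1e-4)
  # determinism
  mc2 <- apparent_t2_mc(fit_stub, n_samples = 2e4, seed = 5)
  expect_identical(mc, mc2)
})

test_that("MC mean converges to the deterministic root under shrinking V_p", {
  p <- relax_ref$t2_bi$serum_rt
  root <- apparent_t2(bi_params(p))
  base_cov <- diag(c(1e-4, 0.03, 0.5, 1.5))^2
  dn <- c("A", "beta", "T2a", "T2b")
  prev <- Inf
  for (scale in c(1, 1e-2, 1e-4)) {
    stubf <- list(estimates = c(A = 1, beta = p[["beta"]], T2a = p[["t2a"]],
                                T2b = p[["t2b"]]),
                  covariance = base_cov * scale)
    dimnames(stubf$covariance) <- list(dn, dn)
    mc <- apparent_t2_mc(stubf, n_samples = 1e4, seed = 9)
    dev <- abs(mc$mean - root)
    expect_lte(dev, max(prev, 2 * mc$sd))
    prev <- dev
  }
})

test_that("covariances inconsistent with the constraints are rejected", {
  stubf <- list(estimates = c(A = 1, beta = 0.5, T2a = 5, T2b = 20),
                covariance = diag(c(1e-6, 100, 1e-4, 1e-4)))
  dimnames(stubf$covariance) <- list(c("A", "beta", "T2a", "T2b"),
                                     c("A", "beta", "T2a", "T2b"))
  expect_error(apparent_t2_mc(stubf, n_samples = 2000, seed = 2),
               "constraints")
})

test_that("V_p equals the exact OLS covariance for a linear model", {
  set.seed(8)
  x <- seq(0, 10, length.out = 40)
  y <- 2 + 0.5 * x + rnorm(40, sd = 0.3)
  model_fn <- function(par, t) par[1] + par[2] * t
  est <- coef(lm(y ~ x)); names(est) <- c("b0", "b1")
  fr <- f19mr:::make_fit_result(est, model_fn, x, y)
  expect_equal(unname(fr$covariance), unname(vcov(lm(y ~ x))),
               tolerance = 1e-7)
})

test_that("CPMG window integration is proportional to echo amplitude", {
  acq <- spectro_acq_params(n_points = 1024L)
  amps <- exp(-(1:6) * 3.2 / 15)
  echoes <- lapply(amps, function(a)
    simulate_spectrum(spectral_model(voigt_peak(a, -59.1, 0.5, 1)), acq))
  win <- hz_window(-59.1, 5000, acq$reference_frequency)
  out <- cpmg_echo_amplitudes(echoes, (1:6) * 3.2, win)
  expect_equal(out$signal / out$signal[1], amps / amps[1], tolerance = 1e-3)
  expect_error(cpmg_echo_amplitudes(echoes, (1:6) * 3.2, c(-900, 900)),
               "axis")
})

test_that("a 5 kHz window captures nearly all of a narrow Lorentzian", {
  # closed form: the Lorentzian area fraction inside +-W/2 is
  # (2/pi) atan(W / w); CPMG echo linewidths from serum T2 are tens of Hz
  w_hz <- 1 / (pi * 5.3e-3)    # ~60 Hz from T2 = 5.3 ms
  frac <- 2 / pi * atan(5000 / w_hz)
  expect_gt(frac, 0.99)
  acq <- spectro_acq_params(n_points = 8192L, dwell_time = 2.5e-5)
  pk <- voigt_peak(1, -59.1, w_hz / acq$reference_frequency, 1)
  sp <- simulate_spectrum(spectral_model(pk), acq)
  win <- hz_window(-59.1, 5000, acq$reference_frequency)
  out <- cpmg_echo_amplitudes(list(sp), 3.2, win)
  expect_equal(out$signal, voigt_area(pk) * frac, tolerance = 0.02)
})
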