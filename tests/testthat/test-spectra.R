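acq_1k <- spectro_acq_params(n_points = 1024L)

test_that("preprocess_fid localizes a pure complex exponential", {
  f0 <- 1000  # Hz above the carrier
  t <- (0:1023) * acq_1k$dwell_time
  x <- fid(exp(2i * pi * f0 * t), acq_1k$dwell_time,
           acq_1k$reference_frequency, acq_1k$carrier_ppm)
  sp <- preprocess_fid(x, zero_pad_to = 16384L)
  pk <- sp$ppm_axis[which.max(Mod(sp$values[1L, ]))]
  expect_equal(pk, acq_1k$carrier_ppm + f0 / acq_1k$reference_frequency,
               tolerance = 1e-3)
})

test_that("zero-padding interpolates without moving the peak", {
  m <- spectral_model(voigt_peak(1, -61, 1, 1))
  x <- simulate_fid(m, acq_1k)
  sp1 <- preprocess_fid(x, zero_pad_to = 2048L)
  sp4 <- preprocess_fid(x, zero_pad_to = 8192L)
  p1 <- sp1$ppm_axis[which.max(Re(sp1$values[1L, ]))]
  p4 <- sp4$ppm_axis[which.max(Re(sp4$values[1L, ]))]
  expect_lt(abs(p1 - p4), sp1$ppm_axis[2] - sp1$ppm_axis[1])
  expect_equal(diff(sp4$ppm_axis[1:2]), diff(sp1$ppm_axis[1:2]) / 4,
               tolerance = 1e-12)
})

test_that("preprocessing is linear in the input", {
  m1 <- spectral_model(voigt_peak(1, -63, 1.5, 1))
  m2 <- spectral_model(voigt_peak(0.5, -55, 0.8, 0.3))
  x1 <- simulate_fid(m1, acq_1k)
  x2 <- simulate_fid(m2, acq_1k)
  xs <- fid(2 * x1$data + x2$data, acq_1k$dwell_time,
            acq_1k$reference_frequency, acq_1k$carrier_ppm)
  s1 <- preprocess_fid(x1, zero_pad_to = 2048L)
  s2 <- preprocess_fid(x2, zero_pad_to = 2048L)
  ss <- preprocess_fid(xs, zero_pad_to = 2048L)
  expect_equal(ss$values, 2 * s1$values + s2$values, tolerance = 1e-12)
})

test_that("filter delay removal and truncation bounds are enforced", {
  acq <- spectro_acq_params(n_points = 64L, filter_delay_points = 8L)
  m <- spectral_model(voigt_peak(1, -59, 4, 1))
  x <- simulate_fid(m, acq)
  expect_equal(as.vector(x$data[1, 1:8]), rep(0 + 0i, 8))
  expect_error(preprocess_fid(x, truncate_to = 8), "filter delay")
  expect_error(preprocess_fid(x, truncate_to = 100), "exceeds")
  sp <- preprocess_fid(x, truncate_to = 64, zero_pad_to = 1024L)
  expect_equal(ncol(sp$values), 1024L)
})

test_that("truncating a noise-dominated FID raises peak SNR (short T2*)", {
  # serum-like T2* = 0.95 ms against a 20 ms acquisition window
  acq <- spectro_acq_params(n_points = 4096L)
  w_ppm <- 1 / (pi * 0.95e-3) / acq$reference_frequency
  m <- spectral_model(voigt_peak(1, -59.1, w_ppm, 1))
  x <- simulate_fid(m, acq, noise = noise_model(2500, seed = 5))
  sp_short <- preprocess_fid(x, 256L, 16384L)
  sp_full <- preprocess_fid(x, 4096L, 16384L)
  expect_gt(peak_snr_of(sp_short), 1.5 * peak_snr_of(sp_full))
})

test_that("phase correction rotates values but never magnitudes", {
  m <- spectral_model(voigt_peak(1, -59, 1, 1))
  sp <- simulate_spectrum(m, acq_1k, noise_sd = 0.01, seed = 2)
  expect_equal(phase_correct(sp, 0, 0)$values, sp$values)
  neg <- phase_correct(sp, pi)
  expect_equal(Re(neg$values), -Re(sp$values), tolerance = 1e-12)
  rot <- phase_correct(sp, 0.7, 0.05)
  expect_equal(Mod(rot$values), Mod(sp$values), tolerance = 1e-12)
})

test_that("simulate_fid yields the Lorentzian Fourier-pair envelope", {
  m <- spectral_model(voigt_peak(1, acq_1k$carrier_ppm, 0.9, 1))
  x <- simulate_fid(m, acq_1k)
  t <- (0:99) * acq_1k$dwell_time
  w_hz <- 0.9 * acq_1k$reference_frequency
  env <- Mod(x$data[1, 1:100])
  expect_equal(env / env[1], exp(-pi * w_hz * t), tolerance = 1e-10)
})

test_that("time- and frequency-domain energies agree (Parseval)", {
  m <- spectral_model(list(voigt_peak(1, -59, 1, 0.7),
                           voigt_peak(0.4, -70, 2, 0.2)))
  x <- simulate_fid(m, acq_1k, noise = noise_model(1e-4, seed = 9))
  sp <- preprocess_fid(x, zero_pad_to = 4096L)
  df_hz <- diff(sp$ppm_axis[1:2]) * sp$reference_frequency
  e_t <- sum(Mod(x$data[1L, ])^2) * x$dwell_time
  e_f <- sum(Mod(sp$values[1L, ])^2) * df_hz
  expect_equal(e_f, e_t, tolerance = 1e-9)
})

test_that("peaks outside the sampled bandwidth are rejected", {
  acq <- spectro_acq_params(dwell_time = 1e-4, n_points = 256L)  # +-5 kHz
  m <- spectral_model(voigt_peak(1, -59 + 20000 / 376.8, 1, 1))
  expect_error(simulate_fid(m, acq), "bandwidth")
})

test_that("drug plus coil-artifact model shows three resonances", {
  acq <- spectro_acq_params(n_points = 2048L)
  m <- artifact_model_from_stats(published_artifact_stats(1), a = 1)
  m$peaks <- list(voigt_peak(1.5, -59.09, 1, 0.8))
  x <- simulate_fid(m, acq)
  sp <- preprocess_fid(x, zero_pad_to = 4096L)
  y <- Re(sp$values[1L, ])
  near <- function(v, win = 4) {
    sel <- abs(sp$ppm_axis - v) < win
    sp$ppm_axis[sel][which.max(y[sel])]
  }
  expect_lt(abs(near(-59.09) - -59.09), 0.3)
  expect_lt(abs(near(-82.96) - -82.96), 1)
  expect_lt(abs(near(-147.9) - -147.9), 1.5)
})

test_that("fit_voigt recovers exact parameters from noiseless spectra", {
  truth <- voigt_peak(1.8, -60.4, 1.3, 0.6)
  sp <- simulate_spectrum(spectral_model(truth), acq_1k)
  fv <- fit_voigt(sp, 1L, mode = "real_with_baseline")
  est <- fv$model$peaks[[1L]]
  for (fld in c("amplitude", "center", "fwhm", "mixing"))
    expect_equal(est[[fld]], truth[[fld]], tolerance = 1e-4)
  expect_true(fv$fit$converged)
})

test_that("fit_voigt centre recovery at SNR 20 stays within 0.02 ppm", {
  truth <- voigt_peak(1, -59.13, 0.89, 1)
  acq <- spectro_acq_params(n_points = 4096L)
  errs <- vapply(1:40, function(s) {
    sp <- simulate_spectrum(spectral_model(truth), acq, noise_sd = 1 / 20,
                            seed = 1000 + s)
    fv <- fit_voigt(sp, 1L, mode = "real_with_baseline",
                    init = spectral_model(truth), restarts = 1L)
    abs(fv$model$peaks[[1L]]$center - truth$center)
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("complex-mode fit recovers an injected zeroth-order phase", {
  truth <- voigt_peak(1.5, -59.1, 1, 0.8, phase = 0.6)
  sp <- simulate_spectrum(spectral_model(truth), acq_1k)
  fv <- fit_voigt(sp, 1L, mode = "complex", init = spectral_model(truth))
  expect_equal(fv$model$peaks[[1L]]$phase, 0.6, tolerance = 1e-3)
})

test_that("spectral metrics scale linearly and reject bad noise regions", {
  truth <- voigt_peak(1, -59, 1, 1)
  m <- spectral_model(truth)
  noise_sd <- 1 / 50
  sp <- simulate_spectrum(m, acq_1k, noise_sd = noise_sd, seed = 77)
  met <- spectral_metrics(sp, m, noise_region = c(-20, -5))
  expect_equal(met$psnr, 50, tolerance = 0.1 * 50)
  m2 <- spectral_model(voigt_peak(2, -59, 1, 1))
  sp2 <- simulate_spectrum(m2, acq_1k, noise_sd = noise_sd, seed = 77)
  met2 <- spectral_metrics(sp2, m2, noise_region = c(-20, -5))
  expect_equal(met2$psnr / met$psnr, 2, tolerance = 0.05)
  expect_equal(met2$anr / met$anr, 2, tolerance = 0.05)
  expect_error(spectral_metrics(sp, m, noise_region = c(-61, -57)),
               "overlaps")
})

test_that("pSNR and ANR are invariant under re-phased global phase", {
  truth <- voigt_peak(1, -59, 1, 1)
  m <- spectral_model(truth)
  sp <- simulate_spectrum(m, acq_1k, noise_sd = 0.02, seed = 3)
  met0 <- spectral_metrics(sp, m, c(-20, -5))
  rot <- phase_correct(sp, 1.1)
  back <- phase_correct(rot, -1.1)
  met1 <- spectral_metrics(back, m, c(-20, -5))
  expect_equal(met1$psnr, met0$psnr, tolerance = 1e-10)
  expect_equal(met1$anr, met0$anr, tolerance = 1e-10)
})

test_that("time-domain round trip reproduces the original FID", {
  m <- spectral_model(voigt_peak(1, acq_1k$carrier_ppm, 1, 1))
  x <- simulate_fid(m, acq_1k)
  sp <- preprocess_fid(x, zero_pad_to = 4096L)
  back <- to_time_domain_envelope(sp, voigt_peak(1, acq_1k$carrier_ppm, 1, 1),
                                  original_length = 1024L)
  expect_equal(back$data[1L, ], x$data[1L, ], tolerance = 1e-9)
  expect_error(to_time_domain_envelope(sp, voigt_peak(1, -59, 1, 1), 99999),
               "exceeds")
})

test_that("envelope refit recovers the serum-RT apparent T2*", {
  # bi-exponential FID envelope with the serum room-temperature parameters
  p <- relax_ref$t2s_bi$serum_rt
  acq <- spectro_acq_params(n_points = 1024L)
  m <- spectral_model(voigt_peak(1, -59.13, 1, 1))
  x <- simulate_fid(m, acq,
                    envelope = list(type = "bi", beta = p[["beta"]],
                                    t2a_ms = p[["t2a"]], t2b_ms = p[["t2b"]]))
  sp <- preprocess_fid(x, zero_pad_to = 1024L)
  env <- to_time_domain_envelope(sp, voigt_peak(1, -59.13, 1, 1), 1024L)
  t_ms <- (0:1023) * acq$dwell_time * 1e3
  keep <- t_ms < 6
  ft <- fit_decay(t_ms[keep], Mod(env$data[1L, keep]), "bi")
  expect_equal(apparent_t2(ft), 0.952, tolerance = 0.03)
})
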