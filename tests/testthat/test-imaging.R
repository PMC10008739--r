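test_that("off-resonance correction applies the documented phase factor", {
  traj <- radial_trajectory(8, 8, n_spokes = 6, samples_per_spoke = 8,
                            ndim = 2, te_ms = 0.14, dwell_ms = 1 / 75)
  ph <- ellipsoid_phantom(list(list(center = c(0, 0), semi_axes = c(2, 2),
                                    amplitude = 1)))
  ks <- simulate_radial_kspace(ph, traj, n_channels = 1)
  kc <- offres_correct(ks, 2000)
  # first sample (j = 1): phase 2*pi * 0.14 ms * 2 kHz = 2*pi*0.28
  ratio <- kc$samples[1, 1, 1] / ks$samples[1, 1, 1]
  expect_equal(Arg(ratio), 2 * pi * 0.28, tolerance = 1e-9)  # 1.7593 rad
  expect_equal(Mod(kc$samples), Mod(ks$samples), tolerance = 1e-12)
  # identity at zero offset and exact inversion
  expect_identical(offres_correct(ks, 0), ks)
  back <- offres_correct(kc, -2000)
  expect_equal(back$samples, ks$samples, tolerance = 1e-12)
})

test_that("simulated off-resonance is undone by the matching correction", {
  traj <- radial_trajectory(8, 8, n_spokes = 6, samples_per_spoke = 8,
                            ndim = 2, te_ms = 0.14, dwell_ms = 1 / 75)
  on_res <- ellipsoid_phantom(list(list(center = c(0, 0),
                                        semi_axes = c(2, 2), amplitude = 1)))
  off_res <- ellipsoid_phantom(list(list(center = c(0, 0),
                                         semi_axes = c(2, 2), amplitude = 1,
                                         delta_f_hz = 2000)))
  k_on <- simulate_radial_kspace(on_res, traj, n_channels = 1)
  k_fix <- offres_correct(simulate_radial_kspace(off_res, traj,
                                                 n_channels = 1), 2000)
  expect_equal(k_fix$samples, k_on$samples, tolerance = 1e-10)
})

test_that("gridding reconstruction is linear in the data", {
  traj <- radial_trajectory(12, 12, n_spokes = 60, samples_per_spoke = 12,
                            ndim = 2)
  ph1 <- ellipsoid_phantom(list(list(center = c(2, 0), semi_axes = c(3, 2),
                                     amplitude = 1)))
  ph2 <- ellipsoid_phantom(list(list(center = c(-2, 1), semi_axes = c(1, 2),
                                     amplitude = 2)))
  k1 <- simulate_radial_kspace(ph1, traj, n_channels = 1)
  k2 <- simulate_radial_kspace(ph2, traj, n_channels = 1)
  ks <- k1; ks$samples <- 1.7 * k1$samples + k2$samples
  i1 <- recon_radial(k1)[[1]]$data
  i2 <- recon_radial(k2)[[1]]$data
  is <- recon_radial(ks)[[1]]$data
  expect_equal(is, 1.7 * i1 + i2, tolerance = 1e-10)
})

test_that("constant k-space reconstructs a centred point", {
  traj <- radial_trajectory(16, 16, n_spokes = 60, samples_per_spoke = 16,
                            ndim = 2)
  ks <- simulate_radial_kspace(ellipsoid_phantom(), traj, n_channels = 1)
  ks$samples[1, , ] <- 1 + 0i
  img <- Mod(recon_radial(ks)[[1]]$data)
  w <- which(img == max(img), arr.ind = TRUE)
  expect_equal(as.vector(w), c(9, 9))   # n = 0 voxel
})

test_that("gridding matches the direct DFT oracle in 2D", {
  traj <- radial_trajectory(12, 12, n_spokes = 50, samples_per_spoke = 12,
                            ndim = 2)
  ph <- ellipsoid_phantom(list(list(center = c(1, -2), semi_axes = c(4, 3),
                                    amplitude = 1, t2_star_ms = 2)))
  ks <- simulate_radial_kspace(ph, traj, noise = noise_model(0.01, 3),
                               n_channels = 1)
  img <- recon_radial(ks)[[1]]$data
  w <- rep(radial_density_weights(traj), each = nrow(traj$directions))
  oracle <- dft_adjoint_oracle(traj, as.vector(ks$samples[1, , ]), w)
  nrmsd <- sqrt(mean(Mod(img - oracle)^2)) / sqrt(mean(Mod(oracle)^2))
  expect_lt(nrmsd, 0.01)
})

test_that("a centred sphere dominates the background at infinite SNR", {
  traj <- radial_trajectory(16, 16, ndim = 3)
  ph <- ellipsoid_phantom(list(list(center = c(0, 0, 0),
                                    semi_axes = c(3, 3, 3), amplitude = 1)))
  img <- Mod(recon_radial(simulate_radial_kspace(ph, traj,
                                                 n_channels = 1))[[1]]$data)
  r1 <- seq(-8, 7)
  g <- expand.grid(x = r1, y = r1, z = r1)
  inside <- (g$x^2 + g$y^2 + g$z^2) <= 2.5^2
  outside <- (g$x^2 + g$y^2 + g$z^2) >= 5^2
  expect_gt(mean(img[inside]) / mean(img[outside]), 10)
})

test_that("prewhitening normalizes and decorrelates channel noise", {
  nm <- noise_model(matrix(c(1, 0.5, 0.5, 1), 2), seed = 6)
  train <- draw_channel_noise(nm, 2e4)
  test_data <- draw_channel_noise(nm, 1e5, seed = 7)
  wh <- prewhiten(train, test_data)
  emp <- Re(wh %*% Conj(t(wh))) / ncol(wh)
  expect_lt(max(abs(emp - diag(2))), 0.05)
  # diagonal covariance scales channels by inverse standard deviations
  nmd <- noise_model(diag(c(4, 9)), seed = 8)
  traind <- draw_channel_noise(nmd, 5e4)
  W <- attr(prewhiten(traind, traind[, 1:10, drop = FALSE]), "whitener")
  expect_equal(Mod(diag(W)), c(1 / 2, 1 / 3), tolerance = 0.03)
  # near-identity covariance gives a near-identity transform
  nmi <- noise_model(diag(2), seed = 9)
  Wi <- attr(prewhiten(draw_channel_noise(nmi, 2e4),
                       matrix(0i, 2, 4)), "whitener")
  expect_lt(max(Mod(Wi - diag(2))), 0.05)
  expect_error(prewhiten(matrix(0i, 2, 40), matrix(0i, 2, 4)),
               "singular|positive")
})

test_that("root sum of squares combines channels as expected", {
  a <- array(complex(real = rnorm(64), imaginary = rnorm(64)), c(8, 8))
  v1 <- image_volume(a, 1)
  expect_equal(rss_combine(list(v1))$data, Mod(a), tolerance = 1e-12)
  expect_equal(rss_combine(list(v1, v1))$data, sqrt(2) * Mod(a),
               tolerance = 1e-12)
  v2 <- image_volume(array(0i, c(4, 4)), 1)
  expect_error(rss_combine(list(v1, v2)), "grid")
})

test_that("RSS of two-channel unit noise follows a chi(4) distribution", {
  set.seed(10)
  n <- 1e5
  rss <- sqrt(matrix(rnorm(4 * n)^2, n) %*% rep(1, 4))
  ks <- suppressWarnings(
    ks.test(as.vector(rss), function(q) pchisq(q^2, df = 4)))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("snr_map corrects the chi-distributed noise mean", {
  # 1 channel: Rayleigh mean sigma*sqrt(pi/2) = 1.2533 sigma
  expect_equal(f19mr:::chi_mean(2), sqrt(pi / 2), tolerance = 1e-12)
  set.seed(12)
  sigma <- 1.7
  noise_rss <- sqrt(matrix(rowSums(matrix(rnorm(2e5 * 4, sd = sigma)^2,
                                          2e5)), 2e5))
  nimg <- image_volume(array(noise_rss, c(50, 40, 100)), 1)
  img <- image_volume(array(34, c(50, 40, 100)), 1)
  sm <- snr_map(img, nimg, n_channels = 2L)
  expect_equal(sm$sigma, sigma, tolerance = 0.02)
  expect_equal(unique(as.vector(sm$data)), 34 / sm$sigma, tolerance = 1e-12)
  img2 <- image_volume(img$data * 2, 1)
  expect_equal(snr_map(img2, nimg, 2L)$data, 2 * sm$data, tolerance = 1e-12)
  zero <- image_volume(array(0, c(50, 40, 100)), 1)
  expect_error(snr_map(img, zero, 2L), "noise")
})

test_that("cluster thresholding keeps blocks and drops isolated voxels", {
  a <- array(0, c(12, 12, 12))
  a[4:6, 4:6, 4:6] <- 10          # 27-voxel block
  a[10, 10, 10] <- 5              # isolated voxel
  sm <- structure(list(data = a, voxel_size_mm = 1), class = "f19_snr_map")
  mask <- cluster_threshold(sm, threshold = 3.5, min_cluster = 2L)
  expect_true(all(mask[4:6, 4:6, 4:6]))
  expect_false(mask[10, 10, 10])
  expect_equal(sum(mask), 27)
  # 6-connectivity separates diagonal neighbours
  b <- array(0, c(4, 4, 4))
  b[1, 1, 1] <- 10; b[2, 2, 2] <- 10
  smb <- structure(list(data = b, voxel_size_mm = 1), class = "f19_snr_map")
  expect_equal(sum(cluster_threshold(smb, 4, 2L, connectivity = 26L)), 2)
  expect_equal(sum(cluster_threshold(smb, 4, 2L, connectivity = 6L)), 0)
})

test_that("pure-background SNR maps yield (almost) empty masks", {
  set.seed(13)
  noise <- sqrt(matrix(rowSums(matrix(rnorm(1e5 * 2)^2, 1e5)), 1e5))
  sm <- structure(list(data = array(noise / f19mr:::chi_mean(2),
                                    c(100, 100, 10)), voxel_size_mm = 1),
                  class = "f19_snr_map")
  mask <- cluster_threshold(sm, threshold = 4, min_cluster = 2L)
  expect_lt(sum(mask), 5)
})

test_that("concentration maps are exact ratios against the reference", {
  img <- image_volume(array(2, c(6, 6)), 1)
  ref <- image_volume(array(2, c(6, 6)), 1)
  cm <- concentration_map(img, ref, ref_conc_um = 3900)
  expect_true(all(cm$data == 3900))
  half <- image_volume(array(1, c(6, 6)), 1)
  expect_true(all(concentration_map(half, ref, 3900)$data == 1950))
  ref0 <- image_volume(array(c(0, rep(2, 35)), c(6, 6)), 1)
  expect_true(is.na(concentration_map(img, ref0, 3900)$data[1, 1]))
})

test_that("protocol sensitivity ratios are time-adjusted means", {
  a <- structure(list(data = array(20, c(5, 5)), voxel_size_mm = 1),
                 class = "f19_snr_map")
  b <- structure(list(data = array(20, c(5, 5)), voxel_size_mm = 1),
                 class = "f19_snr_map")
  expect_equal(protocol_sensitivity_ratio(a, b, 10, 10), 1)
  b2 <- b; b2$data <- b$data * 2
  expect_equal(protocol_sensitivity_ratio(a, b2, 10, 10), 0.5)
  # a twice as sensitive measured in a quarter of the time
  expect_equal(protocol_sensitivity_ratio(b2, a, 10, 40), 4)
  low <- a; low$data <- array(1, c(5, 5))
  expect_error(protocol_sensitivity_ratio(low, b, 10, 10), "empty")
})

test_that("a constructed 3.1-fold sensitivity difference is recovered", {
  set.seed(14)
  base <- array(15 + rnorm(400, sd = 0.5), c(20, 20))
  sa <- structure(list(data = base * 3.1, voxel_size_mm = 1),
                  class = "f19_snr_map")
  sb <- structure(list(data = array(15 + rnorm(400, sd = 0.5), c(20, 20)),
                       voxel_size_mm = 1), class = "f19_snr_map")
  r <- protocol_sensitivity_ratio(sa, sb, 10, 10)
  expect_equal(r, 3.1, tolerance = 0.05)
})

test_that("the full detection loop finds objects without false alarms", {
  # 2D scaled-down version of the end-to-end detection property
  traj <- radial_trajectory(32, 32, ndim = 2, te_ms = 0.14)
  ph <- ellipsoid_phantom(list(list(center = c(4, -3), semi_axes = c(5, 4),
                                    amplitude = 1, t2_star_ms = 0.95,
                                    delta_f_hz = 2000)))
  r1 <- seq(-15.5, 15.5)
  g <- expand.grid(x = r1, y = r1)
  inside <- ((g$x - 4) / 5)^2 + ((g$y + 3) / 4)^2 <= 1
  outside <- ((g$x - 4) / 5)^2 + ((g$y + 3) / 4)^2 > 1.6^2
  cover <- fp <- numeric(8)
  for (s in 1:8) {
    nm <- noise_model(5^2, seed = 100 + s)
    ks <- simulate_radial_kspace(ph, traj, noise = nm, n_channels = 1,
                                 seed = 100 + s)
    res <- run_imaging_pipeline(ks, pipeline_config(delta_f_hz = 2000,
                                                    snr_threshold = 4))
    cover[s] <- mean(res$mask[inside])
    fp[s] <- mean(res$mask[outside])
  }
  expect_gte(mean(cover), 0.95)
  expect_lte(mean(fp), 0.01)
})
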