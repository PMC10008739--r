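# Shared fixtures and independent oracles for the test suite.

# Table-style relaxation parameter sets used throughout (ms).
relax_ref <- list(
  t1 = c(dmso_rt = 553.2, dmso_pt = 802.4, serum_rt = 282.1,
         serum_pt = 321.7, ex_vivo = 272.9),
  t2_bi = list(
    serum_rt = c(beta = 0.880, t2a = 4.7, t2b = 12.9),
    serum_pt = c(beta = 0.405, t2a = 8.0, t2b = 21.7),
    ex_vivo = c(beta = 0.618, t2a = 9.4, t2b = 80.6)),
  t2s_bi = list(
    serum_rt = c(beta = 0.425, t2a = 0.336, t2b = 1.83),
    serum_pt = c(beta = 0.671, t2a = 0.325, t2b = 3.42))
)

bi_params <- function(p) {
  relax_params("bi_exp", 1, beta = p[["beta"]], t2a = p[["t2a"]],
               t2b = p[["t2b"]])
}

# Independent bisection root of the normalized bi-exponential at 1/e.
bisect_apparent_t2 <- function(beta, t2a, t2b, iter = 200) {
  g <- function(t) beta * exp(-t / t2a) + (1 - beta) * exp(-t / t2b) - exp(-1)
  lo <- min(t2a, t2b) / 100
  hi <- 100 * max(t2a, t2b)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Direct discrete adjoint sum x_n = sum_m w_m y_m exp(2 pi i k_m . r_n)
# (the gridding oracle), written with cos/sin to keep it brisk.
dft_adjoint_oracle <- function(traj, y, w, matrix_size = traj$matrix_size,
                               fov_mm = traj$fov_mm) {
  d <- traj$ndim
  voxel <- fov_mm / matrix_size
  S <- nrow(traj$directions)
  kv <- matrix(0, S * length(traj$radii_invmm), d)
  for (j in seq_len(d))
    kv[, j] <- as.vector(outer(traj$directions[, j], traj$radii_invmm)) * voxel
  r1 <- seq(-matrix_size / 2, matrix_size / 2 - 1)
  grid_pts <- as.matrix(expand.grid(rep(list(r1), d)))
  ph <- 2 * pi * (grid_pts %*% t(kv))
  wy <- w * y
  acc <- (cos(ph) %*% wy) + 1i * (sin(ph) %*% wy)
  array(acc, dim = rep(matrix_size, d))
}

# Equivalent diameter of the above-half-maximum region: a PSF width measure
# robust to ring-shaped off-resonance blurring.
psf_halfmax_width <- function(img) {
  a <- img$data / max(img$data)
  n_above <- sum(a > 0.5)
  if (length(dim(a)) == 2L) 2 * sqrt(n_above / pi)
  else 2 * (3 * n_above / (4 * pi))^(1 / 3)
}

# Background pSNR helper for synthetic single-peak spectra.
peak_snr_of <- function(spec, background_ppm = -30) {
  y <- Re(spec$values[1L, ])
  sel <- spec$ppm_axis > background_ppm
  max(y) / stats::sd(y[sel])
}
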