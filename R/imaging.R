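#' Image volume container
#'
#' Real or complex voxel grid with isotropic voxel size; the affine places
#' the grid centre at the origin (RAS axes, voxel centres).
#'
#' @param data 2D or 3D array (real or complex).
#' @param voxel_size_mm voxel edge length, mm (> 0).
#' @return an object of class `f19_volume`.
#' @export
image_volume <- function(data, voxel_size_mm) {
  if (!is_scalar_num(voxel_size_mm) || voxel_size_mm <= 0)
    stop("'voxel_size_mm' must be > 0")
  structure(list(data = data, voxel_size_mm = voxel_size_mm),
            class = "f19_volume")
}

#' @export
print.f19_volume <- function(x, ...) {
  cat(sprintf("<f19_volume> %s, %.3g mm voxels, %s\n",
              paste(dim(x$data), collapse = "x"), x$voxel_size_mm,
              if (is.complex(x$data)) "complex" else "real"))
  invisible(x)
}

#' Off-resonance phase correction of radial k-space
#'
#' Multiplies every sample at spoke position `j` by the delay-dependent
#' unit-modulus factor `exp(2 pi i (TE + (j-1) t_d) df)`, undoing the
#' linear blurring a resonance offset `df` imprints on a centre-out
#' readout. Sample magnitudes are unchanged; correcting with `-df` inverts
#' the operation exactly.
#'
#' @param k an `f19_kspace` object.
#' @param delta_f_hz off-resonance frequency shift in Hz.
#' @param correct_noise_scan also apply the factor to the noise scan
#'   (default `TRUE`, keeping signal and noise paths identical).
#' @return the corrected `f19_kspace`.
#' @export
offres_correct <- function(k, delta_f_hz, correct_noise_scan = TRUE) {
  stopifnot(inherits(k, "f19_kspace"))
  if (delta_f_hz == 0) return(k)
  t_s <- traj_sample_times(k$traj) * 1e-3
  fac <- exp(2i * pi * t_s * delta_f_hz)
  for (j in seq_along(fac)) {
    k$samples[, , j] <- k$samples[, , j] * fac[j]
    if (correct_noise_scan && !is.null(k$noise_scan))
      k$noise_scan[, , j] <- k$noise_scan[, , j] * fac[j]
  }
  k
}

#' Analytic radial density-compensation weights
#'
#' Shell (3D) or annulus (2D) area weights per sample: the k-space volume
#' between radii `r - dk/2` and `r + dk/2` divided by the number of spokes,
#' which assigns the central sample the volume of the innermost
#' half-shell (the DC correction).
#'
#' @param traj an [radial_trajectory()] object.
#' @return numeric vector, one weight per sample along a spoke
#'   (cycles/mm^d units).
#' @export
radial_density_weights <- function(traj) {
  r <- traj$radii_invmm
  dk <- if (length(r) > 1) r[2] - r[1] else max(r, 1)
  lo <- pmax(r - dk / 2, 0)
  hi <- r + dk / 2
  S <- nrow(traj$directions)
  if (traj$ndim == 3L) (4 / 3) * pi * (hi^3 - lo^3) / S
  else pi * (hi^2 - lo^2) / S
}

# Kaiser-Bessel gridding machinery ------------------------------------------

kb_beta <- function(width, os) {
  pi * sqrt((width^2 / os^2) * (os - 0.5)^2 - 0.8)
}

kb_kernel <- function(u, width, beta) {
  x <- 2 * u / width
  out <- numeric(length(u))
  ok <- abs(x) <= 1
  out[ok] <- besselI(beta * sqrt(1 - x[ok]^2), 0) / besselI(beta, 0)
  out
}

# Closed-form transform of the KB kernel at image position n on a grid of
# size G: (W / I0(beta)) * sinh(g)/g with g = sqrt(beta^2 - (pi W n / G)^2)
# (sin for negative radicand).
kb_apodization <- function(n, G, width, beta) {
  g2 <- beta^2 - (pi * width * n / G)^2
  g <- sqrt(abs(g2))
  out <- ifelse(g2 > 0, sinh(g) / g, ifelse(g == 0, 1, sin(g) / g))
  out * width / besselI(beta, 0)
}

# Adjoint non-uniform Fourier transform by convolution gridding:
# approximates x_n = sum_m wy_m exp(+2 pi i k_m . n) for voxel offsets
# n in [-N/2, N/2)^d, k in cycles/voxel.
gridding_adjoint <- function(k_vox, wy, N, os = 2, width = 5) {
  d <- ncol(k_vox)
  G <- as.integer(os * N)
  beta <- kb_beta(width, os)
  u <- k_vox * G
  base <- floor(u - width / 2)
  n_off <- ceiling(width)
  M <- nrow(k_vox)
  # per-dimension kernel weights and wrapped indices, cached once
  wts <- vector("list", d)
  idxs <- vector("list", d)
  for (j in seq_len(d)) {
    wj <- matrix(0, M, n_off)
    ij <- matrix(0L, M, n_off)
    for (o in seq_len(n_off)) {
      p <- base[, j] + o
      wj[, o] <- kb_kernel(u[, j] - p, width, beta)
      ij[, o] <- (p %% G) + 1L
    }
    wts[[j]] <- wj
    idxs[[j]] <- ij
  }
  offs <- as.matrix(expand.grid(rep(list(seq_len(n_off)), d)))
  z <- array(0 + 0i, dim = rep(G, d))
  yre <- Re(wy); yim <- Im(wy)
  for (oi in seq_len(nrow(offs))) {
    wt <- wts[[1L]][, offs[oi, 1L]]
    lin <- idxs[[1L]][, offs[oi, 1L]]
    mult <- 1L
    for (j in seq_len(d)[-1L]) {
      wt <- wt * wts[[j]][, offs[oi, j]]
      mult <- mult * G
      lin <- lin + (idxs[[j]][, offs[oi, j]] - 1L) * mult
    }
    re <- rowsum(yre * wt, lin)
    im <- rowsum(yim * wt, lin)
    idx <- as.integer(rownames(re))
    z[idx] <- z[idx] + complex(real = re[, 1L], imaginary = im[, 1L])
  }
  xg <- fftshift_arr(stats::fft(z, inverse = TRUE))
  c0 <- G / 2 + 1L
  sel <- (c0 - N / 2):(c0 + N / 2 - 1L)
  xc <- if (d == 2L) xg[sel, sel] else xg[sel, sel, sel]
  ap <- kb_apodization(seq(-N / 2, N / 2 - 1), G, width, beta)
  deproj <- if (d == 2L) outer(ap, ap) else outer(outer(ap, ap), ap)
  xc / deproj
}

#' Radial image reconstruction (adjoint NUFFT with density compensation)
#'
#' Grids the density-compensated radial samples with a Kaiser-Bessel
#' kernel (oversampling 2, width 5) onto an oversampled Cartesian grid,
#' inverse-FFTs, crops and deapodizes. The result approximates the direct
#' adjoint sum `x_n = sum_m w_m y_m exp(2 pi i k_m r_n)` and is linear in
#' the data.
#'
#' @param k an `f19_kspace` object.
#' @param matrix_size target matrix (defaults to the trajectory's).
#' @param fov_mm target field of view (defaults to the trajectory's).
#' @param what `"samples"` or `"noise_scan"`.
#' @return list of complex [image_volume()] objects, one per channel.
#' @export
recon_radial <- function(k, matrix_size = NULL, fov_mm = NULL,
                         what = c("samples", "noise_scan")) {
  stopifnot(inherits(k, "f19_kspace"))
  what <- match.arg(what)
  traj <- k$traj
  if (is.null(matrix_size)) matrix_size <- traj$matrix_size
  if (is.null(fov_mm)) fov_mm <- traj$fov_mm
  data <- if (what == "samples") k$samples else k$noise_scan
  if (is.null(data)) stop("no noise scan present in this k-space object")
  voxel_mm <- fov_mm / matrix_size
  if (max(traj$radii_invmm) * voxel_mm > 0.5 + 1e-9)
    stop("trajectory exceeds the Nyquist box of the target grid")
  S <- nrow(traj$directions); J <- length(traj$radii_invmm)
  d <- traj$ndim
  k_vox <- matrix(0, S * J, d)
  for (dim_i in seq_len(d))
    k_vox[, dim_i] <- as.vector(outer(traj$directions[, dim_i],
                                      traj$radii_invmm)) * voxel_mm
  w <- rep(radial_density_weights(traj), each = S)
  out <- vector("list", dim(data)[1L])
  for (ch in seq_along(out)) {
    y <- as.vector(data[ch, , ])
    img <- gridding_adjoint(k_vox, w * y, matrix_size)
    out[[ch]] <- image_volume(img, voxel_mm)
  }
  out
}

#' Noise prewhitening
#'
#' Estimates the channel noise covariance from zero-excitation samples,
#' Cholesky-factorizes it and applies the inverse factor so that the
#' whitened noise has (empirically) identity covariance.
#'
#' @param noise_samples complex matrix `[channel, n]` of noise-only data
#'   (`n >= 10 x` channels).
#' @param data complex matrix `[channel, m]` or `f19_kspace` to transform.
#' @return object of the same kind as `data`, whitened; the whitening
#'   matrix is attached as attribute `"whitener"`.
#' @export
prewhiten <- function(noise_samples, data) {
  nch <- nrow(noise_samples)
  n <- ncol(noise_samples)
  if (n < 10 * nch) stop("need at least 10 noise samples per channel")
  sigma <- noise_samples %*% Conj(t(noise_samples)) / n
  L <- tryCatch(chol_complex(sigma), error = function(e)
    stop("noise covariance is singular or not positive definite"))
  W <- solve(L)
  if (inherits(data, "f19_kspace")) {
    dm <- dim(data$samples)
    flat <- matrix(data$samples, dm[1L])
    data$samples <- array(W %*% flat, dm)
    if (!is.null(data$noise_scan)) {
      flatn <- matrix(data$noise_scan, dm[1L])
      data$noise_scan <- array(W %*% flatn, dm)
    }
    attr(data, "whitener") <- W
    return(data)
  }
  out <- W %*% data
  attr(out, "whitener") <- W
  out
}

#' Root-sum-of-squares channel combination
#'
#' @param channel_images list of complex [image_volume()] objects on one
#'   grid.
#' @return real [image_volume()] with voxelwise `sqrt(sum |c|^2)`.
#' @export
rss_combine <- function(channel_images) {
  if (inherits(channel_images, "f19_volume"))
    channel_images <- list(channel_images)
  ref <- channel_images[[1L]]
  acc <- array(0, dim = dim(ref$data))
  for (ci in channel_images) {
    if (!identical(dim(ci$data), dim(ref$data)) ||
        ci$voxel_size_mm != ref$voxel_size_mm)
      stop("channel images are not on a common grid")
    acc <- acc + Mod(ci$data)^2
  }
  image_volume(sqrt(acc), ref$voxel_size_mm)
}

#' SNR map with channel-count-dependent noise statistics
#'
#' The root-sum-of-squares of `Nc` unit-variance complex Gaussian channels
#' follows a chi distribution with `2 Nc` degrees of freedom, whose mean is
#' `sigma sqrt(2) Gamma(Nc + 1/2) / Gamma(Nc)`. The underlying per-channel
#' Gaussian sd is therefore estimated from the mean of the RSS noise image
#' by that correction (`mean / 1.2533` for one channel), and SNR is signal
#' divided by that sd.
#'
#' @param img real [image_volume()] (RSS-combined magnitude image).
#' @param noise_img matching RSS image of a noise-only acquisition.
#' @param n_channels number of RF channels entering the RSS.
#' @return object of class `f19_snr_map`: `data` (SNR), `voxel_size_mm`,
#'   `sigma` (estimated per-channel noise sd).
#' @export
snr_map <- function(img, noise_img, n_channels = 1L) {
  stopifnot(inherits(img, "f19_volume"), inherits(noise_img, "f19_volume"))
  mu <- mean(noise_img$data)
  if (!is.finite(mu) || mu <= 0) stop("noise image has non-positive mean")
  sigma <- mu / chi_mean(2 * n_channels)
  structure(list(data = img$data / sigma,
                 voxel_size_mm = img$voxel_size_mm, sigma = sigma,
                 n_channels = n_channels),
            class = "f19_snr_map")
}

#' Cluster-based thresholding of an SNR map
#'
#' Voxels above `threshold` are grouped into connected components
#' (26-neighbourhood in 3D, 8 in 2D by default); clusters smaller than
#' `min_cluster` voxels are discarded as noise peaks.
#'
#' @param snr an `f19_snr_map` (or [image_volume()]).
#' @param threshold SNR cutoff (3.5 for in vivo, 4.0 for ex vivo data).
#' @param min_cluster minimum surviving cluster size in voxels.
#' @param connectivity 26 or 6 (3D), 8 or 4 (2D).
#' @return logical mask array of class `f19_mask` with attribute
#'   `"labels"` (integer cluster labels, 0 = background).
#' @export
cluster_threshold <- function(snr, threshold = 4, min_cluster = 2L,
                              connectivity = NULL) {
  stopifnot(threshold > 0)
  a <- snr$data
  dims <- dim(a)
  d <- length(dims)
  if (is.null(connectivity)) connectivity <- if (d == 3L) 26L else 8L
  supra <- which(a > threshold)
  labels <- array(0L, dims)
  if (length(supra) > 0L) {
    offs <- as.matrix(expand.grid(rep(list(-1:1), d)))
    offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
    if (connectivity %in% c(6L, 4L))
      offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
    coords <- arrayInd(supra, dims)
    edges <- NULL
    for (oi in seq_len(nrow(offs))) {
      nb <- sweep(coords, 2L, offs[oi, ], `+`)
      ok <- rep(TRUE, nrow(nb))
      for (j in seq_len(d)) ok <- ok & nb[, j] >= 1L & nb[, j] <= dims[j]
      if (!any(ok)) next
      lin <- nb[ok, 1L]
      mult <- 1L
      for (j in seq_len(d)[-1L]) {
        mult <- mult * dims[j - 1L]
        lin <- lin + (nb[ok, j] - 1L) * mult
      }
      tgt <- match(lin, supra)
      src <- which(ok)[!is.na(tgt)]
      tgt <- tgt[!is.na(tgt)]
      if (length(tgt)) edges <- rbind(edges, cbind(src, tgt))
    }
    g <- igraph::graph_from_edgelist(
      rbind(edges, cbind(seq_along(supra), seq_along(supra))),
      directed = FALSE)
    comp <- igraph::components(g)
    keep_comp <- which(comp$csize >= min_cluster)
    memb <- comp$membership[seq_along(supra)]
    sel <- memb %in% keep_comp
    relabel <- match(memb, keep_comp)
    labels[supra[sel]] <- relabel[sel]
  }
  mask <- labels > 0L
  structure(mask, labels = labels, threshold = threshold,
            min_cluster = min_cluster, class = c("f19_mask", class(mask)))
}

#' Concentration map against a reference phantom
#'
#' Voxelwise signal-intensity ratio between the image and a co-registered
#' reference-phantom image, multiplied by the known reference
#' concentration. A `scale_factor` accounts for deliberate protocol
#' differences (e.g. differing numbers of averages scale the signal
#' linearly). Voxels with non-positive reference SI inside the mask are
#' returned as `NA` (flagged invalid).
#'
#' @param img real [image_volume()].
#' @param ref_img matching reference [image_volume()].
#' @param ref_conc_um reference concentration in uM.
#' @param mask optional `f19_mask`; outside voxels are 0.
#' @param scale_factor signal scale correction (default 1).
#' @return [image_volume()] of concentrations (uM).
#' @export
concentration_map <- function(img, ref_img, ref_conc_um, mask = NULL,
                              scale_factor = 1) {
  stopifnot(inherits(img, "f19_volume"), inherits(ref_img, "f19_volume"))
  if (!identical(dim(img$data), dim(ref_img$data)))
    stop("image and reference grids differ")
  conc <- img$data / ref_img$data * ref_conc_um * scale_factor
  bad <- ref_img$data <= 0
  conc[bad] <- NA_real_
  if (!is.null(mask)) conc[!mask] <- 0
  image_volume(conc, img$voxel_size_mm)
}

#' Scan-time-adjusted protocol sensitivity ratio
#'
#' Mean voxelwise SNR ratio of two co-registered SNR maps over the voxels
#' exceeding `snr_min` in both, multiplied by `sqrt(ta_b / ta_a)` to
#' normalize for acquisition time (SNR grows with the square root of
#' time). An additional `adjust` factor exposes any further normalization
#' (e.g. averages vs wall time).
#'
#' @param snr_a,snr_b `f19_snr_map` objects on one grid.
#' @param ta_a,ta_b acquisition times (same unit).
#' @param snr_min joint-mask threshold (default 10).
#' @param adjust extra multiplicative factor (default 1).
#' @return scalar sensitivity ratio (protocol a relative to b).
#' @export
protocol_sensitivity_ratio <- function(snr_a, snr_b, ta_a, ta_b,
                                       snr_min = 10, adjust = 1) {
  if (!identical(dim(snr_a$data), dim(snr_b$data)))
    stop("SNR maps are not on a common grid")
  joint <- snr_a$data > snr_min & snr_b$data > snr_min
  if (!any(joint)) stop("joint mask is empty")
  mean(snr_a$data[joint] / snr_b$data[joint]) * sqrt(ta_b / ta_a) * adjust
}
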