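#' Spectroscopy acquisition parameters
#'
#' @param dwell_time seconds per complex point (default 5e-6, i.e. a 200 kHz
#'   acquisition bandwidth).
#' @param n_points number of complex points (>= 16).
#' @param carrier_ppm chemical shift of the receiver centre.
#' @param reference_frequency spectrometer frequency in MHz (19F at 9.4 T
#'   by default).
#' @param n_channels number of receive channels (>= 1).
#' @param filter_delay_points leading distorted points (>= 0).
#' @return an object of class `f19_acq`.
#' @export
spectro_acq_params <- function(dwell_time = 5e-6, n_points = 2048L,
                               carrier_ppm = -59,
                               reference_frequency = 376.8,
                               n_channels = 1L, filter_delay_points = 0L) {
  if (!is_scalar_num(dwell_time) || dwell_time <= 0)
    stop("'dwell_time' must be > 0")
  if (n_points < 16L) stop("'n_points' must be >= 16")
  if (n_channels < 1L) stop("'n_channels' must be >= 1")
  if (filter_delay_points < 0L) stop("'filter_delay_points' must be >= 0")
  structure(list(dwell_time = dwell_time, n_points = as.integer(n_points),
                 carrier_ppm = carrier_ppm,
                 reference_frequency = reference_frequency,
                 n_channels = as.integer(n_channels),
                 filter_delay_points = as.integer(filter_delay_points)),
            class = "f19_acq")
}

#' Multi-channel complex noise model
#'
#' Circularly symmetric complex Gaussian thermal noise with a Hermitian
#' positive-definite channel covariance (real and imaginary parts i.i.d.
#' within a channel, each with variance `diag(Sigma)/2`).
#'
#' @param channel_covariance Hermitian positive-definite matrix (signal
#'   units squared); a scalar is treated as a 1x1 matrix.
#' @param seed integer seed used when the model is drawn from.
#' @return an object of class `f19_noise`.
#' @export
noise_model <- function(channel_covariance = 1, seed = 1L) {
  if (is.null(dim(channel_covariance)))
    channel_covariance <- diag(channel_covariance, length(channel_covariance))
  sig <- channel_covariance
  if (max(Mod(sig - Conj(t(sig)))) > 1e-10 * max(Mod(sig)))
    stop("channel covariance must be Hermitian")
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("channel covariance must be positive definite")
  structure(list(covariance = sig, seed = as.integer(seed),
                 chol = chol_complex(as.matrix(sig) + 0i)),
            class = "f19_noise")
}

#' Draw correlated complex channel noise
#'
#' @param noise an [noise_model()] object.
#' @param n number of time/k-space samples.
#' @param seed optional override of the model's seed; `NA` draws from the
#'   current RNG stream.
#' @return complex matrix `[channel, n]` with `E[z z^H] = Sigma`.
#' @export
draw_channel_noise <- function(noise, n, seed = NULL) {
  stopifnot(inherits(noise, "f19_noise"))
  nch <- nrow(noise$covariance)
  if (is.null(seed)) seed <- noise$seed
  gen <- function() {
    u <- matrix(complex(real = rnorm(nch * n), imaginary = rnorm(nch * n)),
                nch, n) / sqrt(2)
    noise$chol %*% u
  }
  if (length(seed) == 1L && is.na(seed)) gen() else with_seed(seed, gen())
}

#' Simulate a multi-channel FID from a spectral model
#'
#' Synthesizes the causal time-domain signal whose discrete Fourier
#' transform reproduces the model line shape (pseudo-Voigt components map to
#' exponential and Gaussian time envelopes). Each peak must lie inside the
#' sampled bandwidth. An `envelope` specification replaces the
#' line-shape-implied decay of all peaks with an explicit mono- or
#' bi-exponential envelope (then `amplitude` is the initial time-domain
#' amplitude). The model's first-order phase is applied as a constant phase
#' per peak evaluated at the peak centre; within-line variation of the
#' first-order term is not modelled in the time domain.
#'
#' @param model an [spectral_model()] object.
#' @param acq an [spectro_acq_params()] object.
#' @param envelope `NULL`, or a list `list(type = "mono", t2_ms = ...)` /
#'   `list(type = "bi", beta = ..., t2a_ms = ..., t2b_ms = ...)`, or a list
#'   of such lists (one per peak).
#' @param noise `NULL` or an [noise_model()] object with `n_channels` rows.
#' @param seed optional seed overriding the noise model's.
#' @return an [fid()] object with `n_channels` rows.
#' @export
simulate_fid <- function(model, acq, envelope = NULL, noise = NULL,
                         seed = NULL) {
  stopifnot(inherits(model, "f19_model"), inherits(acq, "f19_acq"))
  peaks <- flatten_model_peaks(model)
  nyq <- 1 / (2 * acq$dwell_time)
  n_sig <- acq$n_points - acq$filter_delay_points
  if (n_sig < 1L) stop("filter delay leaves no signal samples")
  t <- (seq_len(n_sig) - 1) * acq$dwell_time
  s <- rep(0 + 0i, n_sig)
  if (!is.null(envelope) && !is.null(envelope$type))
    envelope <- rep(list(envelope), length(peaks))
  for (i in seq_along(peaks)) {
    pk <- peaks[[i]]
    f0 <- (pk$center - acq$carrier_ppm) * acq$reference_frequency
    if (abs(f0) >= nyq)
      stop(sprintf("peak at %.2f ppm (%.0f Hz) is outside the sampled bandwidth (+-%.0f Hz)",
                   pk$center, f0, nyq))
    env <- if (is.null(envelope)) {
      lineshape_envelope(t, pk$fwhm * acq$reference_frequency, pk$mixing)
    } else {
      decay_envelope(t, envelope[[i]])
    }
    s <- s + pk$amplitude * exp(-1i * pk$phase) * env * exp(2i * pi * f0 * t)
  }
  data <- matrix(rep(s, each = acq$n_channels), acq$n_channels, n_sig)
  if (acq$filter_delay_points > 0L) {
    pad <- matrix(0 + 0i, acq$n_channels, acq$filter_delay_points)
    data <- cbind(pad, data)
  }
  if (!is.null(noise)) {
    if (nrow(noise$covariance) != acq$n_channels)
      stop("noise model channel count does not match acquisition")
    data <- data + draw_channel_noise(noise, ncol(data), seed)
  }
  fid(data, acq$dwell_time, acq$reference_frequency, acq$carrier_ppm,
      acq$filter_delay_points)
}

# Expand coupled doublet into plain peaks; first-order phase folded in as a
# constant per-peak phase at the peak centre.
flatten_model_peaks <- function(model) {
  peaks <- model$peaks
  if (!is.null(model$coupled)) {
    cp <- model$coupled
    ph1 <- cp$p + cp$phi * (cp$v1 - model$pivot_ppm)
    ph2 <- cp$q + cp$phi * (cp$v2 - model$pivot_ppm)
    peaks <- c(peaks, list(
      voigt_peak(cp$a * cp$r, cp$v1, cp$w1, cp$m1, ph1),
      voigt_peak(cp$a * (1 - cp$r), cp$v2, cp$w2, cp$m2, ph2)))
  }
  peaks
}

# Causal time envelope whose transform is a unit-height pseudo-Voigt of
# FWHM w_hz (Hz): Lorentzian part pi*w*exp(-pi w t), Gaussian part with the
# matching half-Gaussian prefactor.
lineshape_envelope <- function(t, w_hz, m) {
  lor <- pi * w_hz * exp(-pi * w_hz * t)
  sigf <- w_hz / (2 * sqrt(2 * log(2)))
  alpha <- 2 * pi^2 * sigf^2
  gau <- 2 * sigf * sqrt(2 * pi) * exp(-alpha * t^2)
  m * lor + (1 - m) * gau
}

decay_envelope <- function(t, spec) {
  t_ms <- t * 1e3
  if (spec$type == "mono") {
    exp(-t_ms / spec$t2_ms)
  } else if (spec$type == "bi") {
    if (spec$beta < 0 || spec$beta > 1) stop("'beta' must lie in [0, 1]")
    spec$beta * exp(-t_ms / spec$t2a_ms) +
      (1 - spec$beta) * exp(-t_ms / spec$t2b_ms)
  } else stop("unknown envelope type: ", spec$type)
}

#' Simulate a spectrum directly in the frequency domain
#'
#' Evaluates a spectral model on the ppm axis implied by the acquisition
#' parameters (or a supplied axis) and adds white complex Gaussian noise of
#' standard deviation `noise_sd` per real/imaginary component, independently
#' per channel.
#'
#' @inheritParams simulate_fid
#' @param noise_sd per-component noise standard deviation (signal units).
#' @param ppm_axis optional explicit axis; defaults to the axis
#'   [preprocess_fid()] would produce at `zero_pad_to = acq$n_points`.
#' @param n_channels number of identical-signal channels to generate.
#' @return an [mr_spectrum()] object.
#' @export
simulate_spectrum <- function(model, acq, noise_sd = 0, seed = NULL,
                              ppm_axis = NULL, n_channels = acq$n_channels) {
  stopifnot(inherits(model, "f19_model"))
  if (is.null(ppm_axis)) {
    n <- acq$n_points
    f_hz <- (seq_len(n) - 1 - n / 2) / (n * acq$dwell_time)
    ppm_axis <- f_hz / acq$reference_frequency + acq$carrier_ppm
  }
  clean <- eval_spectral_model(model, ppm_axis)
  vals <- matrix(rep(clean, each = n_channels), n_channels, length(ppm_axis))
  if (noise_sd > 0) {
    vals <- vals + with_seed(seed, matrix(
      complex(real = rnorm(length(vals), sd = noise_sd),
              imaginary = rnorm(length(vals), sd = noise_sd)),
      n_channels, length(ppm_axis)))
  }
  mr_spectrum(vals, ppm_axis, acq$reference_frequency, acq$carrier_ppm,
              noise_sd = if (noise_sd > 0) noise_sd else NULL)
}

#' Simulate a relaxation series
#'
#' Saturation recovery `S(TR) = A (1 - exp(-TR/T1))` or mono/bi-exponential
#' decay `S(t) = A (beta exp(-t/T2a) + (1 - beta) exp(-t/T2b))`, with
#' additive Gaussian noise.
#'
#' @param kind `"saturation_recovery"`, `"echo_decay"` or `"fid_decay"`
#'   (the latter two share the exponential-decay form; the label records the
#'   provenance of the series).
#' @param params an [relax_params()] object matching `kind`.
#' @param timing repetition or echo times in ms, strictly positive and
#'   sorted increasing.
#' @param noise_sd Gaussian noise standard deviation (signal units).
#' @param seed integer seed for reproducibility.
#' @return a data.frame with columns `time` (ms) and `signal`.
#' @export
simulate_relaxation_series <- function(kind = c("saturation_recovery",
                                                "echo_decay", "fid_decay"),
                                       params, timing, noise_sd = 0,
                                       seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "f19_relax_params"))
  if (any(timing <= 0)) stop("'timing' must be strictly positive")
  if (is.unsorted(timing, strictly = TRUE)) stop("'timing' must be sorted increasing")
  s <- relax_signal(params, timing, kind)
  if (noise_sd > 0) s <- s + with_seed(seed, rnorm(length(s), sd = noise_sd))
  data.frame(time = timing, signal = s)
}

relax_signal <- function(params, t, kind) {
  A <- params$amplitude
  if (kind == "saturation_recovery") {
    if (params$model != "t1_satrec") stop("params do not describe a T1 model")
    A * (1 - exp(-t / params$t1))
  } else {
    if (params$model == "mono_exp") {
      A * exp(-t / params$t2)
    } else if (params$model == "bi_exp") {
      if (params$beta < 0 || params$beta > 1) stop("'beta' must lie in [0, 1]")
      A * (params$beta * exp(-t / params$t2a) +
             (1 - params$beta) * exp(-t / params$t2b))
    } else stop("params do not describe a decay model")
  }
}

#' Coil-intrinsic artifact line statistics
#'
#' Returns the characterized two-line contaminant model of the cryogenic
#' two-channel 19F probe as per-parameter means and standard deviations,
#' ready to use as a Gaussian prior for constrained fitting or as a
#' generator of synthetic control spectra. The two coupled lines sit near
#' -83 and -147 ppm; their amplitudes are `r * a` and `(1 - r) * a` so the
#' fractions sum to one by construction.
#'
#' @param channel RF channel index, 1 or 2.
#' @return object of class `f19_artifact_stats` with elements `channel`,
#'   `means` and `sds` (named vectors over `r, v1, w1, m1, v2, w2, m2`).
#' @export
published_artifact_stats <- function(channel) {
  if (!channel %in% c(1L, 2L)) stop("'channel' must be 1 or 2")
  if (channel == 1L) {
    means <- c(r = 0.84, v1 = -82.96, w1 = 5.1, m1 = 0.82,
               v2 = -147.9, w2 = 6, m2 = 0.8)
    sds <- c(r = 0.02, v1 = 0.08, w1 = 0.4, m1 = 0.06,
             v2 = 0.4, w2 = 1, m2 = 0.2)
  } else {
    means <- c(r = 0.85, v1 = -82.5, w1 = 4.8, m1 = 0.79,
               v2 = -146.9, w2 = 5, m2 = 0.7)
    sds <- c(r = 0.01, v1 = 0.1, w1 = 0.3, m1 = 0.06,
             v2 = 0.4, w2 = 1, m2 = 0.2)
  }
  structure(list(channel = as.integer(channel), means = means, sds = sds),
            class = "f19_artifact_stats")
}

#' Materialize a coupled artifact model from line statistics
#'
#' With `seed = NULL` the means are used; with a seed, each constrained
#' parameter is drawn from its Gaussian (r and mixing clamped to \[0, 1\],
#' widths floored at 10% of the mean) to emulate scan-to-scan variation.
#'
#' @param stats an `f19_artifact_stats` object (or any list with `means`
#'   and `sds`).
#' @param a joint amplitude.
#' @param phi first-order phase (rad/ppm).
#' @param p,q zeroth-order phases of the two lines (rad).
#' @param pivot_ppm first-order phase pivot.
#' @param seed optional integer seed to draw parameters from the prior.
#' @return an [spectral_model()] with only a coupled component.
#' @export
artifact_model_from_stats <- function(stats, a = 1, phi = 0, p = 0, q = 0,
                                      pivot_ppm = -59, seed = NULL) {
  par <- stats$means
  if (!is.null(seed)) {
    par <- with_seed(seed, rnorm(length(stats$means), stats$means, stats$sds))
    names(par) <- names(stats$means)
    par[c("r", "m1", "m2")] <- pmin(pmax(par[c("r", "m1", "m2")], 0), 1)
    par[c("w1", "w2")] <- pmax(par[c("w1", "w2")], 0.1 * stats$means[c("w1", "w2")])
  }
  spectral_model(coupled = list(a = a, phi = phi, r = par[["r"]], p = p, q = q,
                                v1 = par[["v1"]], w1 = par[["w1"]], m1 = par[["m1"]],
                                v2 = par[["v2"]], w2 = par[["w2"]], m2 = par[["m2"]]),
                 pivot_ppm = pivot_ppm)
}

#' Ellipsoid phantom
#'
#' Piecewise-constant test object made of ellipsoids (3D) or ellipses (2D),
#' each with its own amplitude, T2* and off-resonance, for which the Fourier
#' transform is analytic.
#'
#' @param ellipsoids list of lists with fields `center` (mm), `semi_axes`
#'   (mm, all > 0), `amplitude` (>= 0), `t2_star_ms` (> 0 or `Inf`),
#'   `delta_f_hz`.
#' @return an object of class `f19_phantom`.
#' @export
ellipsoid_phantom <- function(ellipsoids = list()) {
  for (e in ellipsoids) {
    if (any(e$semi_axes <= 0)) stop("semi-axes must be > 0")
    if (e$amplitude < 0) stop("amplitude must be >= 0")
    if (!is.null(e$t2_star_ms) && e$t2_star_ms <= 0)
      stop("t2_star_ms must be > 0 (use Inf for no decay)")
  }
  defaults <- list(t2_star_ms = Inf, delta_f_hz = 0)
  ellipsoids <- lapply(ellipsoids, function(e) modifyList(defaults, e))
  structure(list(ellipsoids = ellipsoids), class = "f19_phantom")
}

#' Radial (UTE) k-space trajectory
#'
#' Centre-out radial spokes with uniform direction coverage: a spherical
#' Fibonacci (golden-angle) distribution in 3D, golden-angle increments in
#' 2D. Sample `j` on every spoke is acquired at `TE + (j - 1) * dwell` and
#' sits at radius `(j - 1) * dk` with `dk = 0.5 / samples_per_spoke` cycles
#' per voxel (2x readout oversampling at the default
#' `samples_per_spoke = matrix_size`).
#'
#' @param matrix_size image matrix size per dimension (isotropic).
#' @param fov_mm field of view in mm (isotropic).
#' @param n_spokes number of spokes; default is full angular Nyquist
#'   sampling (`pi * N^2` in 3D, `pi * N` in 2D) divided by `undersampling`.
#' @param samples_per_spoke readout points per spoke.
#' @param te_ms echo time (time of the first sample), ms.
#' @param dwell_ms frequency-encoding dwell time, ms.
#' @param ndim 2 or 3.
#' @param undersampling radial undersampling factor (records intent and
#'   scales the default spoke count).
#' @return an object of class `f19_traj` with unit `directions`
#'   `[spoke, dim]`, `radii_invmm` (cycles/mm per sample) and timing.
#' @export
radial_trajectory <- function(matrix_size, fov_mm, n_spokes = NULL,
                              samples_per_spoke = matrix_size,
                              te_ms = 0.14, dwell_ms = 1 / 75,
                              ndim = 3L, undersampling = 1) {
  stopifnot(ndim %in% c(2L, 3L))
  N <- as.integer(matrix_size)
  if (is.null(n_spokes)) {
    full <- if (ndim == 3L) ceiling(pi * N^2) else ceiling(pi * N)
    n_spokes <- ceiling(full / undersampling)
  }
  S <- as.integer(n_spokes)
  if (ndim == 3L) {
    i <- seq_len(S)
    z <- -1 + 2 * (i - 0.5) / S
    az <- i * pi * (3 - sqrt(5))          # golden angle in radians
    rho <- sqrt(pmax(1 - z^2, 0))
    dirs <- cbind(rho * cos(az), rho * sin(az), z)
  } else {
    ang <- (seq_len(S) - 1) * pi * (sqrt(5) - 1) / 2      # 111.246 deg
    dirs <- cbind(cos(ang), sin(ang))
  }
  J <- as.integer(samples_per_spoke)
  voxel_mm <- fov_mm / N
  dk_vox <- 0.5 / J
  radii_vox <- (seq_len(J) - 1) * dk_vox
  structure(list(directions = dirs, radii_invmm = radii_vox / voxel_mm,
                 matrix_size = N, fov_mm = fov_mm, te_ms = te_ms,
                 dwell_ms = dwell_ms, ndim = as.integer(ndim),
                 undersampling = undersampling),
            class = "f19_traj")
}

#' Sample times of a radial trajectory
#'
#' @param traj an [radial_trajectory()] object.
#' @return times in ms, one per sample along a spoke.
#' @export
traj_sample_times <- function(traj) {
  traj$te_ms + (seq_along(traj$radii_invmm) - 1) * traj$dwell_ms
}

# Analytic Fourier transform of a uniform ellipsoid/ellipse at k (cycles/mm).
ellipsoid_ft <- function(k, center, semi_axes, amplitude) {
  d <- ncol(k)
  scaled <- sweep(k, 2L, semi_axes[seq_len(d)], `*`)
  q <- 2 * pi * sqrt(rowSums(scaled^2))
  if (d == 3L) {
    vol <- 4 / 3 * pi * prod(semi_axes[1:3])
    shape <- ifelse(q < 1e-6, 1 - q^2 / 10,
                    3 * (sin(q) - q * cos(q)) / q^3)
  } else {
    vol <- pi * prod(semi_axes[1:2])
    shape <- ifelse(q < 1e-6, 1 - q^2 / 8, 2 * besselJ(q, 1) / q)
  }
  phase <- exp(-2i * pi * as.vector(k %*% center[seq_len(d)]))
  amplitude * vol * shape * phase
}

#' Simulate radial UTE k-space of an ellipsoid phantom
#'
#' Evaluates the analytic phantom transform at every trajectory sample,
#' applies per-object T2* decay `exp(-t/T2*)` and off-resonance precession
#' `exp(-2 pi i df t)` at the per-sample time `TE + (j-1) dwell`, and adds
#' correlated complex channel noise. A matching zero-excitation noise scan
#' is produced on request.
#'
#' @param phantom an [ellipsoid_phantom()] object (may be empty: the output
#'   is then noise only).
#' @param traj an [radial_trajectory()] object.
#' @param noise `NULL` or an [noise_model()] object.
#' @param n_channels number of receive channels.
#' @param channel_sens `NULL` (uniform) or a function
#'   `(center_mm, channel) -> complex scalar` evaluated at each object
#'   centre, emulating smooth coil-sensitivity variation.
#' @param noise_scan if `TRUE` and `noise` given, also simulate a
#'   noise-only acquisition of identical geometry.
#' @param seed optional seed (overrides the noise model's).
#' @return object of class `f19_kspace`: `samples[channel, spoke, point]`,
#'   `traj`, optional `noise_scan`.
#' @export
simulate_radial_kspace <- function(phantom, traj, noise = NULL,
                                   n_channels = 1L, channel_sens = NULL,
                                   noise_scan = TRUE, seed = NULL) {
  stopifnot(inherits(phantom, "f19_phantom"), inherits(traj, "f19_traj"))
  if (!is.null(noise) && nrow(noise$covariance) != n_channels)
    stop("noise model channel count does not match 'n_channels'")
  S <- nrow(traj$directions)
  J <- length(traj$radii_invmm)
  d <- traj$ndim
  k <- matrix(0, S * J, d)             # spoke-major: sample (s, j) at row (j-1)*S + s
  for (dim_i in seq_len(d))
    k[, dim_i] <- as.vector(outer(traj$directions[, dim_i], traj$radii_invmm))
  t_s <- rep(traj_sample_times(traj), each = S) * 1e-3   # seconds
  base <- rep(0 + 0i, S * J)
  per_obj <- vector("list", length(phantom$ellipsoids))
  for (oi in seq_along(phantom$ellipsoids)) {
    e <- phantom$ellipsoids[[oi]]
    sig <- ellipsoid_ft(k, e$center, e$semi_axes, e$amplitude)
    if (is.finite(e$t2_star_ms)) sig <- sig * exp(-t_s * 1e3 / e$t2_star_ms)
    if (e$delta_f_hz != 0) sig <- sig * exp(-2i * pi * e$delta_f_hz * t_s)
    per_obj[[oi]] <- sig
  }
  samples <- array(0 + 0i, dim = c(n_channels, S, J))
  for (ch in seq_len(n_channels)) {
    acc <- base
    for (oi in seq_along(per_obj)) {
      w <- if (is.null(channel_sens)) 1 else
        channel_sens(phantom$ellipsoids[[oi]]$center, ch)
      acc <- acc + w * per_obj[[oi]]
    }
    samples[ch, , ] <- acc
  }
  nscan <- NULL
  if (!is.null(noise)) {
    nz <- draw_channel_noise(noise, S * J, seed)
    for (ch in seq_len(n_channels))
      samples[ch, , ] <- samples[ch, , ] + matrix(nz[ch, ], S, J)
    if (noise_scan) {
      seed2 <- if (is.null(seed)) noise$seed + 1L else seed + 1L
      nz2 <- draw_channel_noise(noise, S * J, seed2)
      nscan <- array(0 + 0i, dim = c(n_channels, S, J))
      for (ch in seq_len(n_channels)) nscan[ch, , ] <- matrix(nz2[ch, ], S, J)
    }
  }
  structure(list(samples = samples, traj = traj, noise_scan = nscan),
            class = "f19_kspace")
}
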