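#' Free induction decay container
#'
#' Multi-channel complex time-domain MR signal. Rows are receive channels,
#' columns are complex sample points acquired every `dwell_time` seconds.
#' `reference_frequency` (MHz) converts Hz offsets from the receiver centre
#' to ppm; `carrier_ppm` is the chemical shift of the receiver centre on the
#' reference scale (CFCl3 = 0 ppm, drug resonances at negative ppm).
#' `filter_delay_points` counts leading samples distorted by the digital
#' receive filter, dropped during preprocessing.
#'
#' @param data complex matrix `[channel, point]` (a vector is treated as one
#'   channel).
#' @param dwell_time seconds per complex point (> 0).
#' @param reference_frequency spectrometer frequency in MHz.
#' @param carrier_ppm chemical shift at the receiver centre.
#' @param filter_delay_points integer >= 0.
#' @return an object of class `f19_fid`.
#' @export
fid <- function(data, dwell_time, reference_frequency = 376.8,
                carrier_ppm = -59, filter_delay_points = 0L) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  if (!is.complex(data)) data <- matrix(as.complex(data), nrow = nrow(data))
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    stop("FID contains non-finite values")
  if (!is_scalar_num(dwell_time) || dwell_time <= 0)
    stop("'dwell_time' must be > 0")
  if (filter_delay_points < 0) stop("'filter_delay_points' must be >= 0")
  structure(list(data = data, dwell_time = dwell_time,
                 reference_frequency = reference_frequency,
                 carrier_ppm = carrier_ppm,
                 filter_delay_points = as.integer(filter_delay_points)),
            class = "f19_fid")
}

#' @export
print.f19_fid <- function(x, ...) {
  cat(sprintf("<f19_fid> %d channel(s) x %d points, dwell %.3g us, %.1f MHz, carrier %.2f ppm\n",
              nrow(x$data), ncol(x$data), x$dwell_time * 1e6,
              x$reference_frequency, x$carrier_ppm))
  invisible(x)
}

#' Spectrum container
#'
#' Complex frequency-domain signal on a strictly increasing ppm axis. Values
#' follow the continuous-transform convention `S(f) = dt * sum_n s_n
#' exp(-2 pi i f n dt)`, so peak heights are independent of zero-padding.
#'
#' @param values complex matrix `[channel, bin]` or vector (one channel).
#' @param ppm_axis numeric, strictly monotone increasing, one entry per bin.
#' @param reference_frequency MHz, for ppm/Hz conversion.
#' @param carrier_ppm chemical shift at the receiver centre.
#' @param noise_sd optional noise standard deviation (signal units, per
#'   real/imaginary component).
#' @return an object of class `f19_spectrum`.
#' @export
mr_spectrum <- function(values, ppm_axis, reference_frequency = 376.8,
                        carrier_ppm = -59, noise_sd = NULL) {
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  if (ncol(values) != length(ppm_axis))
    stop("length of ppm axis must match number of bins")
  d <- diff(ppm_axis)
  if (any(d <= 0)) stop("ppm axis must be strictly increasing")
  structure(list(values = values, ppm_axis = ppm_axis,
                 reference_frequency = reference_frequency,
                 carrier_ppm = carrier_ppm, noise_sd = noise_sd),
            class = "f19_spectrum")
}

#' @export
print.f19_spectrum <- function(x, ...) {
  cat(sprintf("<f19_spectrum> %d channel(s) x %d bins, %.2f .. %.2f ppm\n",
              nrow(x$values), ncol(x$values), min(x$ppm_axis), max(x$ppm_axis)))
  invisible(x)
}

#' Extract one channel of a spectrum
#'
#' @param spec an `f19_spectrum`.
#' @param channel channel index.
#' @export
get_channel <- function(spec, channel) {
  stopifnot(inherits(spec, "f19_spectrum"))
  if (channel < 1 || channel > nrow(spec$values)) stop("channel out of range")
  mr_spectrum(spec$values[channel, , drop = FALSE], spec$ppm_axis,
           spec$reference_frequency, spec$carrier_ppm, spec$noise_sd)
}

#' FID to spectrum preprocessing
#'
#' Removes the digital-filter delay, truncates the time-domain data,
#' zero-pads and Fourier-transforms to a carrier-centred ppm axis.
#' `truncate_to` is a raw-sample cutoff: samples
#' `filter_delay_points + 1 .. truncate_to` are kept, so truncation to fewer
#' points than the filter delay is rejected. Truncating a long, noise-
#' dominated FID raises spectral SNR for short-T2* signals.
#'
#' @param x an [fid()] object.
#' @param truncate_to raw-sample cutoff (defaults to all samples).
#' @param zero_pad_to transform length after zero padding (defaults to
#'   16384, never less than the kept samples).
#' @return an [mr_spectrum()] object with one row per channel.
#' @export
preprocess_fid <- function(x, truncate_to = NULL, zero_pad_to = 16384L) {
  stopifnot(inherits(x, "f19_fid"))
  n_raw <- ncol(x$data)
  if (is.null(truncate_to)) truncate_to <- n_raw
  if (truncate_to > n_raw) stop("'truncate_to' exceeds available points")
  if (truncate_to <= x$filter_delay_points)
    stop("'truncate_to' must exceed the filter delay (",
         x$filter_delay_points, " points)")
  keep <- (x$filter_delay_points + 1L):truncate_to
  n_keep <- length(keep)
  n_pad <- max(as.integer(zero_pad_to), n_keep)
  nch <- nrow(x$data)
  vals <- matrix(0 + 0i, nch, n_pad)
  for (ch in seq_len(nch)) {
    s <- c(x$data[ch, keep], rep(0 + 0i, n_pad - n_keep))
    vals[ch, ] <- fftshift_vec(stats::fft(s)) * x$dwell_time
  }
  f_hz <- (seq_len(n_pad) - 1 - n_pad / 2) / (n_pad * x$dwell_time)
  ppm <- f_hz / x$reference_frequency + x$carrier_ppm
  mr_spectrum(vals, ppm, x$reference_frequency, x$carrier_ppm)
}

#' Zeroth/first-order phase correction
#'
#' Multiplies the spectrum by `exp(-i (phi0 + phi1 * (ppm - pivot)))`.
#' A unit-modulus factor: the magnitude spectrum is unchanged.
#'
#' @param spec an [mr_spectrum()] object.
#' @param phi0 zeroth-order phase (rad).
#' @param phi1 first-order phase (rad/ppm).
#' @param pivot pivot frequency in ppm (default: the carrier).
#' @export
phase_correct <- function(spec, phi0 = 0, phi1 = 0, pivot = NULL) {
  stopifnot(inherits(spec, "f19_spectrum"))
  if (is.null(pivot)) pivot <- spec$carrier_ppm
  fac <- exp(-1i * (phi0 + phi1 * (spec$ppm_axis - pivot)))
  spec$values <- sweep(spec$values, 2L, fac, `*`)
  spec
}

#' Back-transform a spectrum around one peak to a time-domain envelope
#'
#' Circularly shifts the spectrum so `peak$center` sits at the axis centre
#' (demodulating the resonance to 0 Hz), applies the inverse transform and
#' cuts the series to `original_length` samples. The magnitude of the
#' result is the decay envelope used for T2* fitting.
#'
#' @param spec single-channel [mr_spectrum()] object.
#' @param peak an [voigt_peak()] giving the centre to demodulate.
#' @param original_length number of time samples to keep.
#' @return an [fid()] object (single channel).
#' @export
to_time_domain_envelope <- function(spec, peak, original_length) {
  stopifnot(inherits(spec, "f19_spectrum"))
  if (nrow(spec$values) != 1L)
    stop("expected a single-channel spectrum; use get_channel() or combine_channels()")
  n <- ncol(spec$values)
  if (original_length > n) stop("'original_length' exceeds series length")
  if (peak$center < min(spec$ppm_axis) || peak$center > max(spec$ppm_axis))
    stop("peak centre outside the spectral axis")
  dppm <- spec$ppm_axis[2] - spec$ppm_axis[1]
  centre_bin <- n / 2 + 1                      # bin carrying f = 0
  peak_bin <- which.min(abs(spec$ppm_axis - peak$center))
  shift <- round(centre_bin - peak_bin)
  v <- as.vector(spec$values[1L, ])
  if (shift != 0) {
    shift <- ((shift %% n) + n) %% n
    v <- c(v[(n - shift + 1L):n], v[1L:(n - shift)])
  }
  df_hz <- dppm * spec$reference_frequency
  dt <- 1 / (n * df_hz)
  s <- stats::fft(ifftshift_vec(v), inverse = TRUE) / (n * dt)
  fid(s[seq_len(original_length)], dwell_time = dt,
      reference_frequency = spec$reference_frequency,
      carrier_ppm = peak$center)
}

#' Restrict a spectrum to a ppm interval
#'
#' Localized fits (one resonance plus a low-order baseline) are far less
#' sensitive to distant spectral structure than whole-axis fits; cropping
#' is the standard preparation step for them.
#'
#' @param spec an [mr_spectrum()] object.
#' @param range length-2 ppm interval to keep.
#' @return the cropped [mr_spectrum()].
#' @export
crop_spectrum <- function(spec, range) {
  stopifnot(inherits(spec, "f19_spectrum"), length(range) == 2L)
  sel <- spec$ppm_axis >= min(range) & spec$ppm_axis <= max(range)
  if (sum(sel) < 8L) stop("cropped region contains too few bins")
  mr_spectrum(spec$values[, sel, drop = FALSE], spec$ppm_axis[sel],
              spec$reference_frequency, spec$carrier_ppm, spec$noise_sd)
}
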