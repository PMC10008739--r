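#' Fit Voigt peaks to a spectrum
#'
#' Nonlinear least-squares fit (Levenberg-Marquardt, [minpack.lm::nls.lm])
#' of `n_peaks` Voigt lines to a single-channel spectrum. In
#' `"real_with_baseline"` mode the real part is fitted together with a
#' polynomial baseline of degree <= 2; in `"complex"` mode real and
#' imaginary parts are fitted jointly and each peak carries a free
#' zeroth-order phase. Up to `restarts` perturbed re-initializations (fixed
#' perturbation seed) guard against the shallow Voigt likelihood; a fit that
#' never converges is returned flagged, not silently dropped.
#'
#' @param spec single-channel [mr_spectrum()] object.
#' @param n_peaks number of Voigt lines.
#' @param init optional [spectral_model()] carrying initial peaks; defaults
#'   to automatic peak picking on the real part.
#' @param mode `"real_with_baseline"` or `"complex"`.
#' @param convention line-shape convention (see [voigt_profile()]).
#' @param restarts maximum number of starts (>= 1).
#' @param baseline_degree polynomial degree (0-2) in real mode.
#' @return list with elements `model` (fitted [spectral_model()]) and `fit`
#'   (parameters, Jacobian-based covariance, residual variance, convergence
#'   flag, per-peak areas).
#' @export
fit_voigt <- function(spec, n_peaks = 1L, init = NULL,
                      mode = c("real_with_baseline", "complex"),
                      convention = c("pseudo", "faddeeva"),
                      restarts = 5L, baseline_degree = 2L) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  stopifnot(inherits(spec, "f19_spectrum"))
  if (nrow(spec$values) != 1L)
    stop("fit_voigt() expects a single-channel spectrum")
  f <- spec$ppm_axis
  y <- as.vector(spec$values[1L, ])
  dppm <- f[2] - f[1]
  n_bl <- if (mode == "real_with_baseline") baseline_degree + 1L else 0L

  init_peaks <- if (!is.null(init)) {
    if (length(init$peaks) < n_peaks) stop("init provides too few peaks")
    init$peaks[seq_len(n_peaks)]
  } else {
    pick_peaks(f, Re(y), n_peaks, dppm)
  }
  for (pk in init_peaks)
    if (pk$center < min(f) || pk$center > max(f))
      stop("initial peak centre outside the spectral axis")

  per <- if (mode == "complex") 5L else 4L
  pack <- function(peaks, bl = rep(0, n_bl)) {
    p <- unlist(lapply(peaks, function(pk) {
      base <- c(pk$amplitude, pk$center, pk$fwhm, pk$mixing)
      if (mode == "complex") c(base, pk$phase) else base
    }))
    c(p, bl)
  }
  unpack <- function(par) {
    peaks <- lapply(seq_len(n_peaks), function(i) {
      o <- (i - 1L) * per
      voigt_peak(par[o + 1], par[o + 2], max(par[o + 3], dppm / 4),
                 min(max(par[o + 4], 0), 1),
                 if (mode == "complex") par[o + 5] else 0)
    })
    bl <- if (n_bl > 0) par[n_peaks * per + seq_len(n_bl)] else numeric(0)
    list(peaks = peaks, baseline = bl)
  }
  model_of <- function(par) {
    u <- unpack(par)
    spectral_model(u$peaks, baseline = u$baseline,
                   pivot_ppm = spec$carrier_ppm, convention = convention)
  }
  resid_fn <- function(par) {
    m <- model_of(par)
    pred <- eval_spectral_model(m, f)
    if (mode == "real_with_baseline") Re(y) - Re(pred)
    else c(Re(y) - Re(pred), Im(y) - Im(pred))
  }

  lo <- rep(c(-Inf, min(f), dppm / 4, 0, if (mode == "complex") -2 * pi),
            n_peaks)
  hi <- rep(c(Inf, max(f), diff(range(f)), 1, if (mode == "complex") 2 * pi),
            n_peaks)
  lo <- c(lo, rep(-Inf, n_bl)); hi <- c(hi, rep(Inf, n_bl))

  p0 <- pack(init_peaks)
  best <- NULL
  perturb <- with_seed(20191L, matrix(rnorm(length(p0) * restarts, sd = 0.1),
                                      length(p0), restarts))
  for (attempt in seq_len(max(1L, restarts))) {
    p_try <- p0
    if (attempt > 1L) {
      scale <- pmax(abs(p0), c(rep(c(1, dppm * 10, dppm * 10, 0.2,
                                     if (mode == "complex") 0.5), n_peaks),
                               rep(1e-3, n_bl)))
      p_try <- p0 + perturb[, attempt] * scale
      p_try <- pmin(pmax(p_try, lo + 1e-12), hi - 1e-12)
    }
    ans <- tryCatch(
      minpack.lm::nls.lm(p_try, lower = lo, upper = hi, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(ans)) next
    ok <- ans$info %in% 1:4 && all(is.finite(ans$par))
    if (is.null(best) || (ok && ans$deviance < best$deviance * (1 - 1e-10))) {
      best <- ans
      best$converged <- ok
    }
    if (!is.null(best) && isTRUE(best$converged)) break
  }
  if (is.null(best)) stop("optimizer failed on all starts")

  par <- best$par
  u <- unpack(par)
  J <- num_jacobian(resid_fn, par)
  vc <- vp_covariance(J, resid_fn(par))
  areas <- vapply(u$peaks, voigt_area, numeric(1), convention = convention)
  list(model = model_of(par),
       fit = list(par = par, converged = isTRUE(best$converged),
                  rss = best$deviance, sigma_r2 = vc$sigma_r2,
                  covariance = vc$Vp, std_errors = sqrt(pmax(diag(vc$Vp), 0)),
                  areas = areas, mode = mode, convention = convention,
                  info = best$info))
}

# Greedy peak picking on the real part: take the maximum, estimate the
# half-maximum width, subtract a Lorentzian stand-in, repeat.
pick_peaks <- function(f, yr, n_peaks, dppm) {
  res <- yr
  peaks <- list()
  for (i in seq_len(n_peaks)) {
    j <- which.max(res)
    a <- res[j]; v <- f[j]
    half <- a / 2
    right <- j; while (right < length(f) && res[right] > half) right <- right + 1L
    left <- j; while (left > 1L && res[left] > half) left <- left - 1L
    w <- max((f[min(right, length(f))] - f[max(left, 1L)]), 2 * dppm)
    peaks[[i]] <- voigt_peak(a, v, w, 0.8, 0)
    res <- res - Re(voigt_profile(f, peaks[[i]]))
  }
  peaks
}

#' Spectral sensitivity metrics: pSNR and ANR
#'
#' The noise standard deviation is estimated from the real part of a
#' peak-free background region of the (combined) spectrum. pSNR is the
#' maximum real peak height over the fitted peaks' windows (+-3 FWHM)
#' divided by the noise level; ANR is the summed fitted Voigt area divided
#' by the noise level (units: ppm). A noise region that overlaps any fitted
#' peak within +-3 FWHM is rejected.
#'
#' @param spec single-channel [mr_spectrum()] object.
#' @param model fitted [spectral_model()]; with an empty model the global
#'   real maximum is reported (degenerate but not an error).
#' @param noise_region length-2 numeric, ppm interval of the background.
#' @return list with `psnr`, `anr`, `noise_sd`.
#' @export
spectral_metrics <- function(spec, model, noise_region) {
  stopifnot(inherits(spec, "f19_spectrum"), length(noise_region) == 2L)
  if (nrow(spec$values) != 1L)
    stop("spectral_metrics() expects a single (combined) channel")
  f <- spec$ppm_axis
  y <- Re(as.vector(spec$values[1L, ]))
  lo <- min(noise_region); hi <- max(noise_region)
  peaks <- flatten_model_peaks(model)
  for (pk in peaks) {
    if (pk$center + 3 * pk$fwhm > lo && pk$center - 3 * pk$fwhm < hi)
      stop(sprintf("noise region overlaps peak at %.2f ppm (+-3 FWHM)",
                   pk$center))
  }
  in_noise <- f >= lo & f <= hi
  if (sum(in_noise) < 8L) stop("noise region contains too few bins")
  noise_sd <- stats::sd(y[in_noise])
  if (length(peaks) == 0L) {
    height <- max(y)
    area <- 0
  } else {
    win <- rep(FALSE, length(f))
    for (pk in peaks)
      win <- win | (abs(f - pk$center) <= 3 * pk$fwhm)
    height <- max(y[win])
    area <- sum(vapply(peaks, voigt_area, numeric(1),
                       convention = model$convention))
  }
  list(psnr = height / noise_sd, anr = area / noise_sd, noise_sd = noise_sd)
}
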