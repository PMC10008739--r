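#' Voigt peak description
#'
#' A single spectral line parameterized by real-part peak amplitude, centre
#' frequency (ppm), full width at half maximum (ppm), Lorentzian/Gaussian
#' mixing parameter `m` in \[0, 1\] (`m = 1` pure Lorentzian, `m = 0` pure
#' Gaussian) and a zeroth-order phase in radians.
#'
#' @param amplitude real-part peak height at the centre (signal units).
#' @param center centre frequency in ppm.
#' @param fwhm full width at half maximum of the real part, in ppm (> 0).
#' @param mixing Lorentzian fraction in \[0, 1\].
#' @param phase zeroth-order phase in radians.
#' @return an object of class `f19_peak`.
#' @export
voigt_peak <- function(amplitude = 1, center = 0, fwhm = 1, mixing = 1,
                       phase = 0) {
  if (!is_scalar_num(fwhm) || fwhm <= 0) stop("'fwhm' must be > 0")
  if (!is_scalar_num(mixing) || mixing < 0 || mixing > 1)
    stop("'mixing' must lie in [0, 1]")
  structure(list(amplitude = amplitude, center = center, fwhm = fwhm,
                 mixing = mixing, phase = phase),
            class = "f19_peak")
}

#' Complex Voigt line shape
#'
#' Evaluates a complex (absorption + dispersion) line shape at frequencies
#' `f`. Two conventions are available:
#'
#' * `"pseudo"` (default): the pseudo-Voigt convex combination
#'   \eqn{m L(f) + (1-m) G(f)} of a unit-height complex Lorentzian and a
#'   unit-height complex Gaussian sharing the same real-part FWHM `w`. The
#'   Gaussian's dispersion part is the exact one-sided-FID transform,
#'   evaluated through the Faddeeva function.
#' * `"faddeeva"`: the true Voigt convolution profile with Lorentzian FWHM
#'   `m * w` and Gaussian FWHM `(1 - m) * w`, evaluated via [faddeeva()] and
#'   normalized to unit real-part height at the centre.
#'
#' Both conventions use the sign convention of a causal FID
#' \eqn{e^{2\pi i f_0 t}} sampled for \eqn{t \ge 0}: the dispersion
#' (imaginary) part is negative just above the centre frequency. With
#' `phase = 0` the real part peaks at `amplitude` at `f = center` and is
#' symmetric about it.
#'
#' @param f frequencies (ppm) at which to evaluate.
#' @param peak an [voigt_peak()] object (or a list with the same fields).
#' @param convention `"pseudo"` or `"faddeeva"`.
#' @return complex vector of the same length as `f`.
#' @export
voigt_profile <- function(f, peak, convention = c("pseudo", "faddeeva")) {
  convention <- match.arg(convention)
  if (peak$fwhm <= 0) stop("'fwhm' must be > 0")
  base <- voigt_shape(f - peak$center, peak$fwhm, peak$mixing, convention)
  peak$amplitude * exp(-1i * peak$phase) * base
}

# Unit-height complex line shape centred at 0.
voigt_shape <- function(delta, w, m, convention) {
  if (convention == "pseudo") {
    gam <- w / 2
    lor <- gam / complex(real = gam, imaginary = delta)
    x <- 2 * sqrt(log(2)) * delta / w
    gau <- faddeeva(as.complex(-x))
    m * lor + (1 - m) * gau
  } else {
    wl <- m * w
    wg <- (1 - m) * w
    if (wg < 1e-9 * w) {            # degenerate: pure Lorentzian
      gam <- wl / 2
      return(gam / complex(real = gam, imaginary = delta))
    }
    sig <- wg / (2 * sqrt(2 * log(2)))
    gam <- wl / 2
    z <- complex(real = -delta, imaginary = gam) / (sig * sqrt(2))
    z0 <- complex(real = 0, imaginary = gam) / (sig * sqrt(2))
    faddeeva(z) / Re(faddeeva(z0))
  }
}

#' Area under the real part of a Voigt peak
#'
#' For the pseudo-Voigt convention the area has the closed form
#' \eqn{a w (m \pi / 2 + (1-m) \sqrt{\pi / \ln 2} / 2)}; for the true-Voigt
#' convention it is obtained by adaptive quadrature. Units: amplitude x ppm.
#'
#' @inheritParams voigt_profile
#' @export
voigt_area <- function(peak, convention = c("pseudo", "faddeeva")) {
  convention <- match.arg(convention)
  a <- peak$amplitude
  w <- peak$fwhm
  m <- peak$mixing
  if (convention == "pseudo") {
    a * w * (m * pi / 2 + (1 - m) * sqrt(pi / log(2)) / 2)
  } else {
    g <- function(d) Re(voigt_shape(d, w, m, "faddeeva"))
    a * 2 * stats::integrate(g, 0, 60 * w, rel.tol = 1e-9)$value
  }
}

#' Spectral model: free Voigt peaks, optional coupled artifact doublet,
#' polynomial baseline
#'
#' The coupled component implements the two-line model
#' \deqn{L(f) = a e^{-i\phi (f - f_p)} (r e^{-ip} V(f; v_1, w_1, m_1) +
#'   (1 - r) e^{-iq} V(f; v_2, w_2, m_2))}
#' with joint amplitude `a`, first-order phase `phi` (rad/ppm, pivoted at
#' `pivot_ppm`), amplitude ratio `r` in \[0, 1\], and zeroth-order phases
#' `p`, `q`. Free peaks carry their own amplitude/phase. The baseline is a
#' real polynomial in (f - pivot_ppm), added to the real part only when a
#' model is evaluated in real mode.
#'
#' @param peaks list of [voigt_peak()] objects (may be empty).
#' @param coupled `NULL`, or a named list/vector with elements
#'   `a, phi, r, p, q, v1, w1, m1, v2, w2, m2`.
#' @param baseline numeric polynomial coefficients (constant first).
#' @param pivot_ppm pivot for first-order phase and baseline.
#' @param convention line-shape convention passed to [voigt_profile()].
#' @return an object of class `f19_model`.
#' @export
spectral_model <- function(peaks = list(), coupled = NULL,
                           baseline = numeric(0), pivot_ppm = 0,
                           convention = c("pseudo", "faddeeva")) {
  convention <- match.arg(convention)
  if (inherits(peaks, "f19_peak")) peaks <- list(peaks)
  if (!is.null(coupled)) {
    coupled <- as.list(coupled)
    need <- c("a", "phi", "r", "p", "q", "v1", "w1", "m1", "v2", "w2", "m2")
    if (!all(need %in% names(coupled)))
      stop("coupled component must provide: ", paste(need, collapse = ", "))
    if (coupled$r < 0 || coupled$r > 1) stop("'r' must lie in [0, 1]")
  }
  structure(list(peaks = peaks, coupled = coupled, baseline = baseline,
                 pivot_ppm = pivot_ppm, convention = convention),
            class = "f19_model")
}

#' Evaluate a spectral model on a frequency axis
#'
#' @param model an [spectral_model()] object.
#' @param f frequencies in ppm.
#' @param component `"all"`, `"coupled"` (artifact doublet only) or
#'   `"peaks"` (free peaks only). The baseline is included only for
#'   `"all"`.
#' @return complex vector.
#' @export
eval_spectral_model <- function(model, f, component = c("all", "coupled",
                                                        "peaks")) {
  component <- match.arg(component)
  out <- rep(0 + 0i, length(f))
  if (component %in% c("all", "coupled") && !is.null(model$coupled)) {
    cp <- model$coupled
    v1 <- voigt_shape(f - cp$v1, cp$w1, cp$m1, model$convention)
    v2 <- voigt_shape(f - cp$v2, cp$w2, cp$m2, model$convention)
    ramp <- exp(-1i * cp$phi * (f - model$pivot_ppm))
    out <- out + cp$a * ramp *
      (cp$r * exp(-1i * cp$p) * v1 + (1 - cp$r) * exp(-1i * cp$q) * v2)
  }
  if (component %in% c("all", "peaks")) {
    for (pk in model$peaks) {
      out <- out + voigt_profile(f, pk, model$convention)
    }
  }
  if (component == "all" && length(model$baseline) > 0) {
    x <- f - model$pivot_ppm
    bl <- rep(0, length(f))
    for (d in seq_along(model$baseline)) bl <- bl + model$baseline[d] * x^(d - 1)
    out <- out + bl
  }
  out
}
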