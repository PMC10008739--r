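#' Artifact prior container
#'
#' Per-channel Gaussian summary (mean, sd) of the coupled two-line coil
#' artifact parameters `(r, v1, w1, m1, v2, w2, m2)`, plus the extra
#' frequency uncertainty added before constrained fitting to absorb field
#' drift: the artifact-centre sds are inflated as
#' `sqrt(sd^2 + (inflation_hz / f0)^2)` with `f0` the reference frequency in
#' MHz.
#'
#' @param channel_stats list of `f19_artifact_stats` objects (one per RF
#'   channel, in channel order).
#' @param frequency_sd_inflation_hz extra centre-frequency standard
#'   deviation in Hz (default 250).
#' @return an object of class `f19_artifact_prior`.
#' @export
artifact_prior <- function(channel_stats,
                           frequency_sd_inflation_hz = 250) {
  if (inherits(channel_stats, "f19_artifact_stats"))
    channel_stats <- list(channel_stats)
  for (st in channel_stats) {
    if (any(st$sds <= 0)) stop("all prior sds must be > 0")
    if (st$means[["r"]] < 0 || st$means[["r"]] > 1)
      stop("prior mean of r must lie in [0, 1]")
  }
  structure(list(channels = channel_stats,
                 frequency_sd_inflation_hz = frequency_sd_inflation_hz),
            class = "f19_artifact_prior")
}

constrained_names <- c("r", "v1", "w1", "m1", "v2", "w2", "m2")

#' Characterize the coil artifact from control spectra
#'
#' Fits the coupled two-Voigt model
#' `L(f) = a e^{-i phi f}(r e^{-ip} V1 + (1-r) e^{-iq} V2)` to each control
#' spectrum (acquired with an empty coil) per channel and summarizes the
#' constrained parameters by their sample mean and standard deviation.
#' Non-convergent individual fits are excluded with a warning; fewer than 3
#' convergent fits per channel is an error.
#'
#' @param control_spectra list of [mr_spectrum()] objects; each may carry
#'   one or several channels (all must agree in channel count and axis).
#' @param frequency_sd_inflation_hz stored in the resulting prior.
#' @param init optional `f19_artifact_stats` used to initialize the fits;
#'   defaults to data-driven peak picking.
#' @return an [artifact_prior()] object.
#' @export
characterize_artifact <- function(control_spectra,
                                  frequency_sd_inflation_hz = 250,
                                  init = NULL) {
  stopifnot(length(control_spectra) >= 3L)
  nch <- nrow(control_spectra[[1L]]$values)
  stats_per_channel <- vector("list", nch)
  for (ch in seq_len(nch)) {
    pars <- list()
    for (si in seq_along(control_spectra)) {
      sp <- get_channel(control_spectra[[si]], ch)
      ft <- tryCatch(fit_coupled_artifact(sp, init = init),
                     error = function(e) NULL)
      if (is.null(ft) || !ft$converged) {
        warning(sprintf("control spectrum %d, channel %d: fit did not converge; excluded",
                        si, ch))
        next
      }
      pars[[length(pars) + 1L]] <- ft$par[constrained_names]
    }
    if (length(pars) < 3L)
      stop(sprintf("channel %d: fewer than 3 convergent control fits", ch))
    pm <- do.call(rbind, pars)
    means <- colMeans(pm)
    sds <- apply(pm, 2L, stats::sd)
    sds <- pmax(sds, 1e-8 * pmax(abs(means), 1))   # identical inputs: sd ~ 0
    stats_per_channel[[ch]] <- structure(
      list(channel = ch, means = means, sds = sds, n_fits = nrow(pm)),
      class = "f19_artifact_stats")
  }
  artifact_prior(stats_per_channel, frequency_sd_inflation_hz)
}

# Unconstrained coupled two-peak fit of one channel. Returns par (named),
# converged flag, rss.
fit_coupled_artifact <- function(spec, init = NULL) {
  f <- spec$ppm_axis
  y <- as.vector(spec$values[1L, ])
  if (is.null(init)) {
    pk <- pick_peaks(f, Re(y), 2L, f[2] - f[1])
    h <- vapply(pk, function(p) p$amplitude, numeric(1))
    ord <- order(h, decreasing = TRUE)
    p1 <- pk[[ord[1]]]; p2 <- pk[[ord[2]]]
    init_par <- c(a = h[ord[1]] + h[ord[2]], phi = 0,
                  r = h[ord[1]] / (h[ord[1]] + h[ord[2]]), p = 0, q = 0,
                  v1 = p1$center, w1 = max(p1$fwhm, 1), m1 = 0.8,
                  v2 = p2$center, w2 = max(p2$fwhm, 1), m2 = 0.8)
  } else {
    m <- init$means
    amp0 <- max(Re(y))
    init_par <- c(a = amp0, phi = 0, r = m[["r"]], p = 0, q = 0,
                  v1 = m[["v1"]], w1 = m[["w1"]], m1 = m[["m1"]],
                  v2 = m[["v2"]], w2 = m[["w2"]], m2 = m[["m2"]])
  }
  fit_artifact_lm(f, y, init_par, prior_resid = NULL, free_peak = FALSE)
}

# Shared Levenberg-Marquardt core for the coupled model, optionally with a
# free third peak and Gaussian prior penalty residuals.
fit_artifact_lm <- function(f, y, init_par, prior_resid = NULL,
                            free_peak = FALSE, drug_window = c(-70, -50),
                            noise_sd = 1, convention = "pseudo",
                            bin_weights = NULL) {
  if (is.null(bin_weights)) bin_weights <- rep(1, length(f))
  nm <- c("a", "phi", "r", "p", "q", "v1", "w1", "m1", "v2", "w2", "m2")
  if (free_peak) nm <- c(nm, "a3", "v3", "w3", "m3", "p3")
  stopifnot(all(nm %in% names(init_par)))
  init_par <- init_par[nm]
  rng <- range(f)
  lo <- c(a = 0, phi = -Inf, r = 0, p = -2 * pi, q = -2 * pi,
          v1 = rng[1], w1 = 0.05, m1 = 0, v2 = rng[1], w2 = 0.05, m2 = 0)
  hi <- c(a = Inf, phi = Inf, r = 1, p = 2 * pi, q = 2 * pi,
          v1 = rng[2], w1 = diff(rng), m1 = 1, v2 = rng[2],
          w2 = diff(rng), m2 = 1)
  if (free_peak) {
    lo <- c(lo, a3 = -Inf, v3 = drug_window[1], w3 = 0.02, m3 = 0,
            p3 = -2 * pi)
    hi <- c(hi, a3 = Inf, v3 = drug_window[2], w3 = 20, m3 = 1, p3 = 2 * pi)
  }
  model_eval <- function(par) {
    m <- spectral_model(coupled = as.list(par[1:11]),
                        convention = convention, pivot_ppm = 0)
    out <- eval_spectral_model(m, f, component = "coupled")
    if (free_peak) {
      pk <- voigt_peak(par[["a3"]], par[["v3"]], par[["w3"]], par[["m3"]],
                       par[["p3"]])
      out <- out + voigt_profile(f, pk, convention)
    }
    out
  }
  resid_fn <- function(par) {
    names(par) <- nm
    d <- (y - model_eval(par)) * bin_weights
    r <- c(Re(d), Im(d)) / noise_sd
    if (!is.null(prior_resid)) r <- c(r, prior_resid(par))
    r
  }
  ans <- tryCatch(
    minpack.lm::nls.lm(init_par, lower = lo, upper = hi, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(ans)) return(list(par = init_par, converged = FALSE, rss = NA))
  par <- ans$par
  names(par) <- nm
  list(par = par, converged = ans$info %in% 1:4 && all(is.finite(par)),
       rss = ans$deviance, info = ans$info,
       model_values = model_eval(par))
}

#' Bayesian-prior-constrained three-peak fit
#'
#' Fits the coupled artifact doublet plus one unconstrained Voigt peak to a
#' tissue spectrum. The seven artifact shape parameters carry standardized
#' Gaussian penalty residuals `sqrt(weight) (theta - mu) / sigma'` where the
#' centre-frequency sds are inflated by the prior's drift allowance (250 Hz
#' by default); amplitude `a`, global phases and the free peak are
#' unpenalized. The free peak is bounded to the drug search window and
#' initialized at the expected drug resonance. A free peak converging to
#' within one FWHM of an artifact centre is flagged, not rejected.
#'
#' @param spec single-channel [mr_spectrum()] object.
#' @param prior an [artifact_prior()].
#' @param channel channel index into the prior.
#' @param drug_window ppm interval allowed for the free peak.
#' @param init_drug_ppm initial free-peak centre.
#' @param prior_weight relative weight of the penalty (default 1).
#' @param noise_sd noise level for residual weighting; by default taken
#'   from the spectrum or estimated robustly from peak-free bins.
#' @param robust if `TRUE` (default), bins carrying coherent residuals
#'   well above the noise level (over 4 sd) that lie away from the
#'   artifact line cores and outside the drug window are down-weighted to
#'   zero and the model is refitted once. This keeps unmodelled
#'   resonances (potential metabolites) from being absorbed into - and
#'   then subtracted with - the artifact tails.
#' @return an object of class `f19_threepeak`: fitted artifact model, free
#'   peak, diagnostics.
#' @export
constrained_fit <- function(spec, prior, channel = 1L,
                            drug_window = c(-70, -50),
                            init_drug_ppm = -59, prior_weight = 1,
                            noise_sd = NULL, robust = TRUE) {
  stopifnot(inherits(spec, "f19_spectrum"),
            inherits(prior, "f19_artifact_prior"))
  if (channel > length(prior$channels)) stop("no prior for channel ", channel)
  st <- prior$channels[[channel]]
  f <- spec$ppm_axis
  y <- as.vector(spec$values[1L, ])
  ref <- spec$reference_frequency
  infl_ppm <- prior$frequency_sd_inflation_hz / ref
  sds <- st$sds
  sds[c("v1", "v2")] <- sqrt(sds[c("v1", "v2")]^2 + infl_ppm^2)
  if (is.null(noise_sd)) {
    noise_sd <- spec$noise_sd
    if (is.null(noise_sd)) {
      quiet <- rep(TRUE, length(f))
      for (v in c(st$means[["v1"]], st$means[["v2"]]))
        quiet <- quiet & abs(f - v) > 5 * max(st$means[c("w1", "w2")])
      quiet <- quiet & (f < drug_window[1] | f > drug_window[2])
      noise_sd <- stats::mad(Re(y[quiet]))
      if (!is.finite(noise_sd) || noise_sd <= 0) noise_sd <- stats::sd(Re(y))
    }
  }
  prior_resid <- function(par) {
    sqrt(prior_weight) * (par[constrained_names] - st$means) / sds
  }
  amp0 <- max(Mod(y))
  win <- f >= drug_window[1] & f <= drug_window[2]
  a3_0 <- max(Re(y[win]))
  init_par <- c(a = amp0, phi = 0, r = st$means[["r"]], p = 0, q = 0,
                st$means[c("v1", "w1", "m1", "v2", "w2", "m2")],
                a3 = max(a3_0, amp0 * 0.01), v3 = init_drug_ppm, w3 = 1,
                m3 = 0.8, p3 = 0)
  names(init_par)[6:11] <- c("v1", "w1", "m1", "v2", "w2", "m2")
  ft <- fit_artifact_lm(f, y, init_par, prior_resid = prior_resid,
                        free_peak = TRUE, drug_window = drug_window,
                        noise_sd = noise_sd)
  n_excluded <- 0L
  if (robust && ft$converged) {
    resid <- y - ft$model_values
    par0 <- ft$par
    protected <- abs(f - par0[["v1"]]) < par0[["w1"]] |
      abs(f - par0[["v2"]]) < par0[["w2"]] |
      (f >= drug_window[1] & f <= drug_window[2])
    excl <- Mod(resid) > 4 * noise_sd & !protected
    if (any(excl)) {
      n_excluded <- sum(excl)
      ft2 <- fit_artifact_lm(f, y, par0, prior_resid = prior_resid,
                             free_peak = TRUE, drug_window = drug_window,
                             noise_sd = noise_sd,
                             bin_weights = as.numeric(!excl))
      if (ft2$converged) ft <- ft2
    }
  }
  par <- ft$par
  collapse <- any(abs(par[["v3"]] - c(par[["v1"]], par[["v2"]])) <
                    par[["w3"]])
  if (collapse)
    warning("free peak converged within one FWHM of an artifact centre")
  artifact_model <- spectral_model(coupled = as.list(par[1:11]),
                                   pivot_ppm = 0)
  free_peak <- voigt_peak(par[["a3"]], par[["v3"]], par[["w3"]],
                          par[["m3"]], par[["p3"]])
  structure(list(artifact_model = artifact_model, free_peak = free_peak,
                 par = par, converged = ft$converged, rss = ft$rss,
                 noise_sd = noise_sd, collapse_flag = collapse,
                 n_excluded_bins = n_excluded, prior_channel = channel),
            class = "f19_threepeak")
}

#' Subtract the fitted artifact component from a spectrum
#'
#' Only the evaluated coupled-doublet portion of the fit is removed; the
#' free peak and any unmodelled features (potential metabolites) are left
#' untouched. Subtracting is linear: applying it twice with the same fit
#' removes the component twice.
#'
#' @param spec the single-channel [mr_spectrum()] the fit was computed on.
#' @param fit an `f19_threepeak` from [constrained_fit()] (must have
#'   converged).
#' @return the cleaned [mr_spectrum()].
#' @export
subtract_artifact <- function(spec, fit) {
  stopifnot(inherits(spec, "f19_spectrum"), inherits(fit, "f19_threepeak"))
  if (!isTRUE(fit$converged)) stop("artifact fit did not converge")
  art <- eval_spectral_model(fit$artifact_model, spec$ppm_axis,
                             component = "coupled")
  spec$values <- sweep(spec$values, 2L, art, `-`)
  spec
}

#' Combine RF channels by phased averaging
#'
#' Each channel is re-phased by its zeroth-order phase and the channels are
#' arithmetically averaged. If `noise_region` is given, the noise sd of the
#' combined spectrum is estimated there and stored.
#'
#' @param spectra list of single-channel [mr_spectrum()] objects on a
#'   common ppm axis, or one multi-channel spectrum.
#' @param phases numeric, zeroth-order phase per channel (rad).
#' @param noise_region optional length-2 ppm interval.
#' @return single-channel combined [mr_spectrum()].
#' @export
combine_channels <- function(spectra, phases = NULL, noise_region = NULL) {
  if (inherits(spectra, "f19_spectrum")) {
    spectra <- lapply(seq_len(nrow(spectra$values)),
                      function(ch) get_channel(spectra, ch))
  }
  nch <- length(spectra)
  if (is.null(phases)) phases <- rep(0, nch)
  if (length(phases) != nch) stop("one phase per channel required")
  f <- spectra[[1L]]$ppm_axis
  acc <- rep(0 + 0i, length(f))
  for (ch in seq_len(nch)) {
    sp <- spectra[[ch]]
    if (length(sp$ppm_axis) != length(f) ||
        max(abs(sp$ppm_axis - f)) > 1e-9 * max(abs(f)))
      stop("channel spectra are not on a common ppm axis")
    acc <- acc + as.vector(sp$values[1L, ]) * exp(-1i * phases[ch])
  }
  out <- mr_spectrum(acc / nch, f, spectra[[1L]]$reference_frequency,
                     spectra[[1L]]$carrier_ppm)
  if (!is.null(noise_region)) {
    sel <- f >= min(noise_region) & f <= max(noise_region)
    out$noise_sd <- stats::sd(Re(out$values[1L, sel]))
  }
  out
}
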