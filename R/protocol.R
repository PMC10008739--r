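#' Ernst angle
#'
#' Flip angle maximizing spoiled gradient-echo steady-state signal:
#' `acos(exp(-TR/T1))`.
#'
#' @param tr repetition time, ms.
#' @param t1 longitudinal relaxation time, ms.
#' @return angle in degrees.
#' @export
ernst_angle <- function(tr, t1) {
  stopifnot(tr > 0, t1 > 0)
  acos(exp(-tr / t1)) * 180 / pi
}

#' Optimal balanced-SSFP flip angle
#'
#' `acos((T1/T2 - 1) / (T1/T2 + 1))`, the on-resonance signal-maximizing
#' excitation angle in the short-TR limit.
#'
#' @param t1,t2 relaxation times, ms (requires `t1 >= t2`).
#' @return angle in degrees.
#' @export
bssfp_optimal_angle <- function(t1, t2) {
  stopifnot(t1 > 0, t2 > 0)
  if (t2 > t1) stop("requires T1 >= T2")
  ratio <- t1 / t2
  acos((ratio - 1) / (ratio + 1)) * 180 / pi
}

#' Steady-state signal of spoiled gradient-echo or bSSFP sequences
#'
#' Spoiled GE (FLASH/UTE):
#' `sin(a) (1 - E1) / (1 - cos(a) E1) * exp(-TE/T2s)` with
#' `E1 = exp(-TR/T1)`. bSSFP (on-resonance):
#' `sin(a) (1 - E1) / (1 - (E1 - E2) cos(a) - E1 E2) * exp(-TE/T2)`.
#' Intended for relative comparisons only.
#'
#' @param seq_type `"spoiled_ge"` or `"bssfp"`.
#' @param tr,te ms.
#' @param alpha_deg flip angle, degrees.
#' @param t1 ms.
#' @param t2 transverse time entering the TE decay (T2* for spoiled GE),
#'   ms; `Inf` disables the TE factor.
#' @return relative signal (dimensionless).
#' @export
steady_state_signal <- function(seq_type = c("spoiled_ge", "bssfp"),
                                tr, te = 0, alpha_deg, t1, t2 = Inf) {
  seq_type <- match.arg(seq_type)
  a <- alpha_deg * pi / 180
  e1 <- exp(-tr / t1)
  te_fac <- if (is.finite(t2)) exp(-te / t2) else 1
  if (seq_type == "spoiled_ge") {
    sin(a) * (1 - e1) / (1 - cos(a) * e1) * te_fac
  } else {
    e2 <- if (is.finite(t2)) exp(-tr / t2) else 1
    sin(a) * (1 - e1) / (1 - (e1 - e2) * cos(a) - e1 * e2) * te_fac
  }
}

#' RARE echo-train point spread function
#'
#' Models the phase-encode k-space line modulation produced by T2 decay
#' along the echo train: the `n_phase` lines are ordered centre-out
#' (`"centric"`) or sequentially (`"linear"`), divided among `etl` echoes
#' (`n_phase/etl` lines each, requiring divisibility), and each line is
#' weighted by the normalized decay at its echo time `e * delta_te`. The
#' PSF is the magnitude of the inverse transform of that modulation,
#' evaluated on a 64-fold refined grid; the FWHM of the central lobe is
#' measured in voxel units by linear interpolation.
#'
#' @param etl echo train length (must divide `n_phase`).
#' @param delta_te echo spacing, ms.
#' @param t2_params [relax_params()] of model `"mono_exp"` or `"bi_exp"`
#'   (normalized; amplitude ignored), or `Inf` T2 via
#'   `relax_params("mono_exp", t2 = Inf)` is not allowed - pass
#'   `t2 = 1e12` for an effectively flat train.
#' @param n_phase number of phase-encode lines.
#' @param ordering `"centric"` or `"linear"`.
#' @return list with `fwhm_voxels`, `x` (voxels), `psf` (magnitude,
#'   unit-normalized), `modulation`.
#' @export
rare_psf <- function(etl, delta_te, t2_params, n_phase = 32L,
                     ordering = c("centric", "linear")) {
  ordering <- match.arg(ordering)
  etl <- as.integer(etl); n_phase <- as.integer(n_phase)
  if (etl > n_phase) stop("'etl' cannot exceed 'n_phase'")
  if (n_phase %% etl != 0L) stop("'etl' must divide 'n_phase'")
  shots <- n_phase %/% etl
  k_idx <- seq(-n_phase / 2, n_phase / 2 - 1)
  rank <- switch(ordering,
                 centric = order(order(abs(k_idx + 0.5))),
                 linear = order(order(k_idx)))
  echo_no <- ceiling(rank / shots)
  decay <- function(t) {
    if (t2_params$model == "mono_exp") exp(-t / t2_params$t2)
    else t2_params$beta * exp(-t / t2_params$t2a) +
      (1 - t2_params$beta) * exp(-t / t2_params$t2b)
  }
  modulation <- decay(echo_no * delta_te)
  refine <- 64L
  x <- seq(-n_phase / 2, n_phase / 2, by = 1 / refine)
  psf <- Mod(exp(2i * pi * outer(x / n_phase, k_idx)) %*% modulation)
  psf <- as.vector(psf) / max(psf)
  centre <- which.max(psf)
  half <- 0.5
  right <- centre
  while (right < length(x) && psf[right] > half) right <- right + 1L
  xr <- stats::approx(psf[c(right - 1L, right)], x[c(right - 1L, right)],
                      xout = half)$y
  left <- centre
  while (left > 1L && psf[left] > half) left <- left - 1L
  xl <- stats::approx(psf[c(left, left + 1L)], x[c(left, left + 1L)],
                      xout = half)$y
  list(fwhm_voxels = xr - xl, x = x, psf = psf, modulation = modulation,
       echo_no = echo_no)
}

#' Highest echo train length with acceptable PSF broadening
#'
#' Scans the divisors of `n_phase` and returns the largest ETL whose RARE
#' PSF FWHM stays below `fwhm_max` voxels.
#'
#' @inheritParams rare_psf
#' @param fwhm_max FWHM criterion in voxels (default 1.5).
#' @return list with `etl` and the per-candidate `fwhm_voxels`.
#' @export
select_rare_etl <- function(delta_te, t2_params, n_phase = 32L,
                            fwhm_max = 1.5, ordering = "centric") {
  cands <- Filter(function(e) n_phase %% e == 0L, seq_len(n_phase))
  fw <- vapply(cands, function(e)
    rare_psf(e, delta_te, t2_params, n_phase, ordering)$fwhm_voxels,
    numeric(1))
  ok <- fw < fwhm_max
  if (!any(ok)) stop("no candidate ETL meets the FWHM criterion")
  list(etl = max(cands[ok]), candidates = cands, fwhm_voxels = fw)
}

#' SNR efficiency
#'
#' `SNR / sqrt(acquisition time in hours)`.
#'
#' @param snr dimensionless SNR.
#' @param ta acquisition time in seconds.
#' @return efficiency in 1/sqrt(h).
#' @export
snr_efficiency <- function(snr, ta) {
  stopifnot(ta > 0)
  snr / sqrt(ta / 3600)
}

#' Rescale a detection limit to a different measurement time
#'
#' Detection limits scale inversely with the square root of measurement
#' time: `limit_new = limit * sqrt(t_ref / t_new)`.
#'
#' @param limit detection limit (e.g. uM) at `t_ref`.
#' @param t_ref,t_new measurement times (same unit).
#' @export
detection_limit_scale <- function(limit, t_ref, t_new) {
  stopifnot(t_ref > 0, t_new > 0)
  limit * sqrt(t_ref / t_new)
}

#' Fluorine atoms per voxel
#'
#' `N_A * concentration * voxel volume * atoms per molecule`, with
#' concentration in mol/L derived from uM and the voxel volume in litres
#' derived from mm^3.
#'
#' @param conc_um concentration in uM.
#' @param voxel_edge_mm isotropic voxel edge in mm (ignored when
#'   `voxel_volume_mm3` given).
#' @param voxel_volume_mm3 voxel volume in mm^3.
#' @param atoms_per_molecule fluorine atoms per molecule (3 for a CF3
#'   group).
#' @export
atoms_per_voxel <- function(conc_um, voxel_edge_mm = NULL,
                            voxel_volume_mm3 = voxel_edge_mm^3,
                            atoms_per_molecule = 3) {
  stopifnot(conc_um >= 0, voxel_volume_mm3 > 0, atoms_per_molecule > 0)
  avogadro <- 6.02214076e23
  conc_mol_l <- conc_um * 1e-6
  vol_l <- voxel_volume_mm3 * 1e-6
  avogadro * conc_mol_l * vol_l * atoms_per_molecule
}

#' Voxel scaling between species
#'
#' Given two brain volumes, returns the voxel-volume ratio giving equal
#' relative spatial resolution and the corresponding isotropic edge-length
#' ratio (its cube root).
#'
#' @param v_a,v_b volumes (same unit, e.g. cm^3).
#' @return list with `volume_ratio`, `edge_ratio`.
#' @export
cross_species_scaling <- function(v_a, v_b) {
  stopifnot(v_a > 0, v_b > 0)
  ratio <- v_a / v_b
  list(volume_ratio = ratio, edge_ratio = ratio^(1 / 3))
}

#' Acquisition-time factor equivalent to an SNR ratio
#'
#' An SNR advantage of factor `x` buys `x^2` faster acquisitions at equal
#' sensitivity.
#'
#' @param snr_ratio SNR ratio (> 0).
#' @export
snr_time_equivalence <- function(snr_ratio) {
  stopifnot(snr_ratio > 0)
  snr_ratio^2
}

#' Dose-proportional concentration scaling
#'
#' Steady-state tissue concentrations scale linearly with dose:
#' `c_ref * dose_new / dose_ref`.
#'
#' @param c_ref reference concentration (e.g. uM).
#' @param dose_ref,dose_new doses (same unit, e.g. mg/kg).
#' @export
dose_scaled_concentration <- function(c_ref, dose_ref, dose_new) {
  stopifnot(c_ref >= 0, dose_ref > 0, dose_new > 0)
  c_ref * dose_new / dose_ref
}
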