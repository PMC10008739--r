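#' Pipeline configuration
#'
#' Central list of stage parameters with the source-protocol defaults: spectra are
#' truncated to 256 raw points and zero-padded to 4096; the artifact-fit
#' drug window is -70..-50 ppm; cluster thresholding uses SNR 4.0 (ex vivo
#' style) with minimum cluster size 2; sensitivity masks use SNR > 10.
#' Every stochastic stage reads its seed from the config. Configs
#' round-trip losslessly through JSON.
#'
#' @param ... overrides of the defaults.
#' @return a list of class `f19_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    truncate_to = 256L,
    zero_pad_to = 4096L,
    drug_window = c(-70, -50),
    init_drug_ppm = -59,
    noise_region = c(-20, -5),
    snr_threshold = 4.0,
    min_cluster = 2L,
    snr_min = 10,
    delta_f_hz = 0,
    seed = 1L,
    verbosity = 0L)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  class(cfg) <- c("f19_config", "list")
  cfg
}

#' Write / read a pipeline config as JSON
#'
#' @param config an [pipeline_config()] list.
#' @param file path.
#' @export
write_config <- function(config, file) {
  jsonlite::write_json(unclass(config), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Spectroscopy pipeline: FID to artifact-cleaned metrics
#'
#' For each sample: preprocess (delay removal, truncation, zero padding,
#' Fourier transform), per-channel constrained three-peak fit against the
#' artifact prior, subtraction of the artifact component, zeroth-order
#' phase correction by the fitted free-peak phase, channel averaging, a
#' final single-Voigt fit on the combined spectrum, and pSNR/ANR metrics.
#'
#' @param fids list of [fid()] objects (or container directories), named
#'   by sample.
#' @param prior an [artifact_prior()]; `NULL` skips the artifact stage
#'   (e.g. volume-coil data without contamination).
#' @param config an [pipeline_config()].
#' @param out_dir optional directory for JSON/CSV reports.
#' @return data.frame with one row per sample: fitted centre (ppm), pSNR,
#'   ANR, noise sd, convergence flag.
#' @export
run_spectro_pipeline <- function(fids, prior = NULL,
                                 config = pipeline_config(),
                                 out_dir = NULL) {
  if (inherits(fids, "f19_fid")) fids <- list(sample = fids)
  rows <- list()
  cleaned <- list()
  for (nm in names(fids)) {
    x <- fids[[nm]]
    if (is.character(x)) x <- run_stage("read", read_fid_container(x))
    spec <- run_stage("preprocess",
                      preprocess_fid(x, config$truncate_to, config$zero_pad_to))
    nch <- nrow(spec$values)
    per_ch <- vector("list", nch)
    phases <- numeric(nch)
    for (ch in seq_len(nch)) {
      sp <- get_channel(spec, ch)
      if (!is.null(prior)) {
        fit3 <- run_stage("artifact_fit",
                          constrained_fit(sp, prior, channel = ch,
                                          drug_window = config$drug_window,
                                          init_drug_ppm = config$init_drug_ppm))
        sp <- run_stage("artifact_subtract", subtract_artifact(sp, fit3))
        # peaks carry exp(-i p); undoing it means correcting with -p
        phases[ch] <- -fit3$free_peak$phase
      } else {
        fv <- run_stage("phase_fit",
                        fit_voigt(sp, 1L, mode = "complex"))
        phases[ch] <- -fv$model$peaks[[1L]]$phase
      }
      per_ch[[ch]] <- phase_correct(sp, phi0 = phases[ch])
    }
    comb <- run_stage("combine",
                      combine_channels(per_ch, phases = rep(0, nch),
                                       noise_region = config$noise_region))
    fv <- run_stage("final_fit",
                    fit_voigt(crop_spectrum(comb, config$drug_window), 1L,
                              mode = "real_with_baseline"))
    met <- run_stage("metrics",
                     spectral_metrics(comb, fv$model, config$noise_region))
    cleaned[[nm]] <- comb
    rows[[nm]] <- data.frame(
      sample = nm, center_ppm = fv$model$peaks[[1L]]$center,
      fwhm_ppm = fv$model$peaks[[1L]]$fwhm, psnr = met$psnr, anr = met$anr,
      noise_sd = met$noise_sd, converged = fv$fit$converged)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "spectro_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(config = unclass(config), report = report),
                         file.path(out_dir, "spectro_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    for (nm in names(cleaned))
      write_spectrum_csv(cleaned[[nm]],
                         file.path(out_dir, paste0("spectrum_", nm, ".csv")))
  }
  report
}

#' Imaging pipeline: k-space to masked (and optionally quantified) maps
#'
#' Off-resonance correction, per-channel gridding reconstruction,
#' root-sum-of-squares combination, SNR mapping against the reconstructed
#' noise scan, cluster thresholding, and - when a reference acquisition is
#' supplied - concentration mapping by signal-intensity ratio.
#'
#' @param kspace `f19_kspace` (with a noise scan) or a container directory.
#' @param config an [pipeline_config()]; `config$delta_f_hz` is the
#'   off-resonance offset to correct.
#' @param reference optional list with fields `kspace` (reference-phantom
#'   acquisition), `conc_um` (its concentration) and optionally
#'   `scale_factor`.
#' @param out_dir optional directory; volumes are written as NIfTI with a
#'   JSON provenance sidecar.
#' @return list with `image`, `snr`, `mask`, optional `concentration`
#'   (and `reference_image`), plus `sigma`.
#' @export
run_imaging_pipeline <- function(kspace, config = pipeline_config(),
                                 reference = NULL, out_dir = NULL) {
  if (is.character(kspace))
    kspace <- run_stage("read", read_kspace_container(kspace))
  if (is.null(kspace$noise_scan))
    stop("pipeline stage 'snr_map' requires a noise scan")
  kc <- run_stage("offres_correct",
                  offres_correct(kspace, config$delta_f_hz))
  nch <- dim(kc$samples)[1L]
  imgs <- run_stage("recon", recon_radial(kc))
  nimgs <- run_stage("recon_noise", recon_radial(kc, what = "noise_scan"))
  img <- run_stage("rss", rss_combine(imgs))
  nimg <- rss_combine(nimgs)
  smap <- run_stage("snr_map", snr_map(img, nimg, n_channels = nch))
  mask <- run_stage("cluster_threshold",
                    cluster_threshold(smap, config$snr_threshold,
                                      config$min_cluster))
  out <- list(image = img, snr = smap, mask = mask, sigma = smap$sigma)
  if (!is.null(reference)) {
    rimgs <- run_stage("recon_reference", recon_radial(
      offres_correct(reference$kspace, config$delta_f_hz)))
    rimg <- rss_combine(rimgs)
    sf <- if (is.null(reference$scale_factor)) 1 else reference$scale_factor
    out$concentration <- run_stage("concentration_map",
                                   concentration_map(img, rimg,
                                                     reference$conc_um,
                                                     mask = mask,
                                                     scale_factor = sf))
    out$reference_image <- rimg
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_volume_nifti(out$image, file.path(out_dir, "image.nii.gz"))
    write_volume_nifti(out$snr, file.path(out_dir, "snr.nii.gz"))
    write_volume_nifti(image_volume(array(as.numeric(attr(mask, "labels")),
                                          dim = dim(out$image$data)),
                                    out$image$voxel_size_mm),
                       file.path(out_dir, "mask.nii.gz"))
    if (!is.null(out$concentration))
      write_volume_nifti(out$concentration,
                         file.path(out_dir, "concentration.nii.gz"))
    jsonlite::write_json(list(config = unclass(config), sigma = smap$sigma,
                              n_channels = nch,
                              n_mask_voxels = sum(mask)),
                         file.path(out_dir, "imaging_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Summarize detected clusters of an imaging-pipeline result
#'
#' For every cluster in the mask: size, peak SNR, and concentration
#' statistics (when a concentration map is present). The hot-spot
#' concentration is reported as the mean over the cluster's peak region -
#' the voxels with SNR at least `peak_frac` of the cluster maximum - which
#' is robust against single-voxel ringing and noise excursions.
#'
#' @param result list returned by [run_imaging_pipeline()].
#' @param peak_frac fraction of the cluster SNR maximum defining the peak
#'   region (default 0.9).
#' @return data.frame sorted by peak SNR (descending): `label`,
#'   `n_voxels`, `peak_snr`, and if available `conc_peak_um` (peak-region
#'   mean), `conc_max_um`, `conc_mean_um`.
#' @export
hotspot_summary <- function(result, peak_frac = 0.9) {
  labels <- attr(result$mask, "labels")
  labs <- sort(unique(labels[labels > 0L]))
  if (length(labs) == 0L) return(data.frame())
  snr <- result$snr$data
  conc <- if (!is.null(result$concentration)) result$concentration$data
  rows <- lapply(labs, function(lb) {
    sel <- labels == lb
    smax <- max(snr[sel])
    peak_sel <- sel & snr >= peak_frac * smax
    row <- data.frame(label = lb, n_voxels = sum(sel), peak_snr = smax)
    if (!is.null(conc)) {
      row$conc_peak_um <- mean(conc[peak_sel], na.rm = TRUE)
      row$conc_max_um <- suppressWarnings(max(conc[sel], na.rm = TRUE))
      row$conc_mean_um <- mean(conc[sel], na.rm = TRUE)
    }
    row
  })
  out <- do.call(rbind, rows)
  out[order(-out$peak_snr), , drop = FALSE]
}
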