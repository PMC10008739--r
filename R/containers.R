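# Plain-text data containers: a directory with a JSON metadata file plus
# CSV arrays. Layout:
#   meta.json                acquisition metadata + content listing
#   fid.csv                  channel, point, re, im
#   kspace.csv               channel, spoke, point, re, im
#   noise_scan.csv           like kspace.csv
#   trajectory.csv           spoke, dim1..dim3 unit direction
# Spectra and fit results are written as standalone CSV/JSON files.

#' Write an FID to a text container
#'
#' @param x an [fid()] object.
#' @param dir directory to create/overwrite.
#' @export
write_fid_container <- function(x, dir) {
  stopifnot(inherits(x, "f19_fid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(kind = "fid", dwell_time = x$dwell_time,
               reference_frequency = x$reference_frequency,
               carrier_ppm = x$carrier_ppm,
               filter_delay_points = x$filter_delay_points,
               n_channels = nrow(x$data), n_points = ncol(x$data))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  idx <- expand.grid(point = seq_len(ncol(x$data)),
                     channel = seq_len(nrow(x$data)))
  df <- data.frame(channel = idx$channel, point = idx$point,
                   re = as.vector(t(Re(x$data))), im = as.vector(t(Im(x$data))))
  utils::write.csv(df, file.path(dir, "fid.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an FID from a text container
#'
#' @param dir container directory written by [write_fid_container()].
#' @return an [fid()] object.
#' @export
read_fid_container <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  if (!identical(meta$kind, "fid")) stop("container does not hold an FID")
  df <- utils::read.csv(file.path(dir, "fid.csv"))
  data <- matrix(complex(real = df$re, imaginary = df$im),
                 nrow = meta$n_channels, ncol = meta$n_points, byrow = TRUE)
  fid(data, meta$dwell_time, meta$reference_frequency, meta$carrier_ppm,
      meta$filter_delay_points)
}

#' Write radial k-space (and its trajectory/noise scan) to a text container
#'
#' @param k an `f19_kspace` object.
#' @param dir directory to create/overwrite.
#' @export
write_kspace_container <- function(k, dir) {
  stopifnot(inherits(k, "f19_kspace"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- k$traj
  meta <- list(kind = "kspace",
               n_channels = dim(k$samples)[1L],
               n_spokes = dim(k$samples)[2L],
               n_points = dim(k$samples)[3L],
               has_noise_scan = !is.null(k$noise_scan),
               trajectory = list(matrix_size = tr$matrix_size,
                                 fov_mm = tr$fov_mm, te_ms = tr$te_ms,
                                 dwell_ms = tr$dwell_ms, ndim = tr$ndim,
                                 undersampling = tr$undersampling,
                                 radii_invmm = tr$radii_invmm))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  dirs <- as.data.frame(tr$directions)
  names(dirs) <- paste0("dim", seq_len(ncol(dirs)))
  utils::write.csv(cbind(spoke = seq_len(nrow(dirs)), dirs),
                   file.path(dir, "trajectory.csv"), row.names = FALSE)
  write_samples <- function(arr, file) {
    dm <- dim(arr)
    idx <- expand.grid(channel = seq_len(dm[1L]), spoke = seq_len(dm[2L]),
                       point = seq_len(dm[3L]))
    utils::write.csv(data.frame(idx, re = Re(as.vector(arr)),
                                im = Im(as.vector(arr))),
                     file.path(dir, file), row.names = FALSE)
  }
  write_samples(k$samples, "kspace.csv")
  if (!is.null(k$noise_scan)) write_samples(k$noise_scan, "noise_scan.csv")
  invisible(dir)
}

#' Read radial k-space from a text container
#'
#' @param dir container directory written by [write_kspace_container()].
#' @return an `f19_kspace` object.
#' @export
read_kspace_container <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  if (!identical(meta$kind, "kspace")) stop("container does not hold k-space")
  tr_meta <- meta$trajectory
  dirs <- utils::read.csv(file.path(dir, "trajectory.csv"))
  dirs <- as.matrix(dirs[, -1L, drop = FALSE])
  traj <- structure(list(directions = unname(dirs),
                         radii_invmm = tr_meta$radii_invmm,
                         matrix_size = tr_meta$matrix_size,
                         fov_mm = tr_meta$fov_mm, te_ms = tr_meta$te_ms,
                         dwell_ms = tr_meta$dwell_ms,
                         ndim = as.integer(tr_meta$ndim),
                         undersampling = tr_meta$undersampling),
                    class = "f19_traj")
  read_samples <- function(file) {
    df <- utils::read.csv(file.path(dir, file))
    arr <- array(complex(real = df$re, imaginary = df$im),
                 dim = c(meta$n_channels, meta$n_spokes, meta$n_points))
    arr
  }
  samples <- read_samples("kspace.csv")
  nscan <- if (isTRUE(meta$has_noise_scan)) read_samples("noise_scan.csv") else NULL
  structure(list(samples = samples, traj = traj, noise_scan = nscan),
            class = "f19_kspace")
}

#' Export a spectrum to CSV (ppm, re, im per channel)
#'
#' @param spec an [mr_spectrum()] object.
#' @param file output path.
#' @export
write_spectrum_csv <- function(spec, file) {
  stopifnot(inherits(spec, "f19_spectrum"))
  nch <- nrow(spec$values)
  dfs <- lapply(seq_len(nch), function(ch) {
    data.frame(channel = ch, ppm = spec$ppm_axis,
               re = Re(spec$values[ch, ]), im = Im(spec$values[ch, ]))
  })
  utils::write.csv(do.call(rbind, dfs), file, row.names = FALSE)
  invisible(file)
}

#' Read a spectrum from CSV
#'
#' @param file path written by [write_spectrum_csv()].
#' @param reference_frequency,carrier_ppm metadata not carried by the CSV.
#' @export
read_spectrum_csv <- function(file, reference_frequency = 376.8,
                              carrier_ppm = -59) {
  df <- utils::read.csv(file)
  chans <- sort(unique(df$channel))
  ppm <- df$ppm[df$channel == chans[1L]]
  vals <- t(vapply(chans, function(ch) {
    sub <- df[df$channel == ch, ]
    complex(real = sub$re, imaginary = sub$im)
  }, complex(length(ppm))))
  mr_spectrum(vals, ppm, reference_frequency, carrier_ppm)
}

#' Serialize an artifact prior to JSON
#'
#' @param prior an [artifact_prior()].
#' @param file output path.
#' @export
write_artifact_prior <- function(prior, file) {
  stopifnot(inherits(prior, "f19_artifact_prior"))
  payload <- list(
    frequency_sd_inflation_hz = prior$frequency_sd_inflation_hz,
    channels = lapply(prior$channels, function(st)
      list(channel = st$channel, means = as.list(st$means),
           sds = as.list(st$sds))))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read an artifact prior from JSON
#'
#' @param file path written by [write_artifact_prior()].
#' @return an [artifact_prior()].
#' @export
read_artifact_prior <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = TRUE)
  chans <- lapply(seq_len(nrow(payload$channels)), function(i) {
    structure(list(channel = payload$channels$channel[i],
                   means = unlist(payload$channels$means[i, ]),
                   sds = unlist(payload$channels$sds[i, ])),
              class = "f19_artifact_stats")
  })
  artifact_prior(chans, payload$frequency_sd_inflation_hz)
}

#' Write an image volume as NIfTI-1
#'
#' Complex volumes are written as magnitude. The affine encodes the voxel
#' size with the grid centre at the origin (RAS).
#'
#' @param vol an [image_volume()] or `f19_snr_map`.
#' @param file output path (`.nii` / `.nii.gz`).
#' @export
write_volume_nifti <- function(vol, file) {
  a <- vol$data
  if (is.complex(a)) a <- Mod(a)
  dm <- dim(a)
  vs <- vol$voxel_size_mm
  arr <- array(as.numeric(a), dim = dm)
  img <- RNifti::asNifti(arr)
  origin <- -vs * (dm[seq_len(min(3L, length(dm)))] / 2 - 0.5)
  aff <- diag(c(rep(vs, 3L), 1))[1:4, 1:4]
  aff[1:3, 4] <- c(origin, rep(0, 3L - length(origin)))[1:3]
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::pixdim(img) <- rep(vs, length(dm))
  RNifti::writeNifti(img, file)
  invisible(file)
}
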