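#' Write a B-scan stack to an HDF5 container
#'
#' One HDF5 file per acquisition. HDF5 carries no native complex type
#' here, so the complex frames are stored as paired double datasets
#' `frames_re` and `frames_im` of shape `n_z x n_x x n_frames`, with the
#' refractive-index profile in `n_of_z` and root attributes
#' `wavelength_nm`, `asu_um`, `frame_rate_hz`, `lateral_sampling_um` and
#' `seed`.
#'
#' @param stack A [bscan_stack()].
#' @param path Output file path (overwritten).
#' @return `path`, invisibly.
#' @export
write_bscan_stack <- function(stack, path) {
  stopifnot(inherits(stack, "bscan_stack"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(Re(stack$frames), path, "frames_re")
  rhdf5::h5write(Im(stack$frames), path, "frames_im")
  rhdf5::h5write(stack$optics$n_of_z, path, "n_of_z")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  o <- stack$optics
  for (a in c("wavelength_nm", "asu_um", "frame_rate_hz", "lateral_sampling_um"))
    rhdf5::h5writeAttribute(o[[a]], fid, a)
  seed <- stack$provenance$seed
  rhdf5::h5writeAttribute(if (is.null(seed)) NA_real_ else as.numeric(seed),
                          fid, "seed")
  invisible(path)
}

#' Read a B-scan stack from an HDF5 container
#'
#' @param path File written by [write_bscan_stack()].
#' @return A [bscan_stack()].
#' @export
read_bscan_stack <- function(path) {
  re <- rhdf5::h5read(path, "frames_re")
  im <- rhdf5::h5read(path, "frames_im")
  n_of_z <- as.numeric(rhdf5::h5read(path, "n_of_z"))
  at <- rhdf5::h5readAttributes(path, "/")
  d <- dim(re)
  optics <- optics_config(
    wavelength_nm = as.numeric(at$wavelength_nm),
    asu_um = as.numeric(at$asu_um),
    frame_rate_hz = as.numeric(at$frame_rate_hz),
    lateral_sampling_um = as.numeric(at$lateral_sampling_um),
    n_frames = d[3], n_z = d[1], n_x = d[2],
    refractive_index_profile = n_of_z)
  seed <- suppressWarnings(as.numeric(at$seed))
  bscan_stack(array(complex(real = re, imaginary = im), dim = d), optics,
              provenance = list(seed = if (length(seed) && is.finite(seed)) seed))
}

#' Write a force trace as CSV
#'
#' Plain CSV with header `time_s,force_gf`.
#'
#' @param trace A [force_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_force_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$time_s,
                              force_gf = trace$force_gf),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a force trace CSV
#'
#' @param path CSV with columns `time_s`, `force_gf`.
#' @return A [force_trace()].
#' @export
read_force_trace <- function(path) {
  df <- utils::read.csv(path)
  force_trace(df$time_s, df$force_gf)
}

#' Write strain maps as a multi-frame 32-bit TIFF
#'
#' One float32 TIFF page per frame pair. TIFF float samples are only
#' well-defined inside `[0, 1]`, so the dimensionless strain is stored
#' through the fixed affine encoding `stored = strain * 10 + 0.5`,
#' covering -5% to +5% axial strain -- beyond the phase-gradient
#' validity bound of the estimator (about 3.2% at 9.5 um sampling).
#' [read_strain_maps()] inverts the encoding.
#'
#' @param strains A `strain_fields` array from [strain_from_xcorr()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strain_maps <- function(strains, path) {
  d <- dim(strains)
  if (any(abs(strains) > 0.05, na.rm = TRUE))
    stop("strain magnitude exceeds the 5% encoding range")
  pages <- lapply(seq_len(d[3]), function(s) strains[, , s] * 10 + 0.5)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read strain maps written by [write_strain_maps()]
#'
#' @param path Multi-frame TIFF path.
#' @return Numeric array `n_z x n_x x n_pages` of dimensionless strain.
#' @export
read_strain_maps <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(NA_real_, dim = c(dim(pages[[1]]), length(pages)))
  for (s in seq_along(pages)) arr[, , s] <- (pages[[s]] - 0.5) / 10
  arr
}

#' Write a region strain series as CSV
#'
#' Header `time_s,eps_ant,eps_nuc,eps_post`, strain in permille.
#'
#' @param series A `region_strain_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Write an oscillation summary (or any result list) as JSON
#'
#' @param x A list-like object (e.g. `oscillation_summary`, `fit_result`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
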