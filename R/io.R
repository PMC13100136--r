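# Stack and result I/O. Multi-page 32-bit-float TIFF output is written by a
# small built-in writer (with stack metadata as a JSON ImageDescription tag),
# since the `tiff` package clamps written values to [0, 1]; reading goes
# through `tiff::readTIFF`, which handles float and integer TIFFs from any
# writer. MRC (mode 2 float / mode 1 int16) support is a minimal MRC2014
# reader/writer with the metadata carried in the first header label.

tiff_tag <- function(con, id, type, count, value) {
  writeBin(as.integer(id), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  writeBin(as.integer(value), con, size = 4, endian = "little")
}

write_tiff_float <- function(data, path, description = NULL) {
  ny <- dim(data)[1]; nx <- dim(data)[2]; nz <- dim(data)[3]
  page_bytes <- ny * nx * 4
  desc <- if (is.null(description)) raw(0) else c(charToRaw(description), as.raw(0))
  data_off <- 8
  desc_off <- data_off + nz * page_bytes
  ifd0 <- desc_off + length(desc)
  if (ifd0 %% 2 == 1) ifd0 <- ifd0 + 1
  n_tags <- function(p) if (p == 1 && length(desc)) 10L else 9L
  ifd_size <- function(p) 2 + 12 * n_tags(p) + 4
  ifd_off <- ifd0 + c(0, cumsum(vapply(seq_len(nz), ifd_size, numeric(1))))[seq_len(nz)]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off[1]), con, size = 4, endian = "little")
  for (p in seq_len(nz))
    writeBin(as.vector(t(data[, , p])), con, size = 4, endian = "little")
  if (length(desc)) writeBin(desc, con)
  if (seek(con) %% 2 == 1) writeBin(as.raw(0), con)
  for (p in seq_len(nz)) {
    writeBin(n_tags(p), con, size = 2, endian = "little")
    tiff_tag(con, 256, 3, 1, nx)
    tiff_tag(con, 257, 3, 1, ny)
    tiff_tag(con, 258, 3, 1, 32)
    tiff_tag(con, 259, 3, 1, 1)             # no compression
    tiff_tag(con, 262, 3, 1, 1)             # black is zero
    if (p == 1 && length(desc))
      tiff_tag(con, 270, 2, length(desc), desc_off)
    tiff_tag(con, 273, 4, 1, data_off + (p - 1) * page_bytes)
    tiff_tag(con, 277, 3, 1, 1)
    tiff_tag(con, 279, 4, 1, page_bytes)
    tiff_tag(con, 339, 3, 1, 3)             # IEEE float
    nxt <- if (p < nz) ifd_off[p + 1] else 0
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

config_metadata <- function(config) {
  list(na = config$na, wavelength = config$wavelength,
       n_immersion = config$n_immersion, voxel = config$voxel,
       pupil_size = config$pupil_size,
       immersion_thickness = config$immersion_thickness)
}

write_mrc <- function(data, path, meta = NULL) {
  ny <- dim(data)[1]; nx <- dim(data)[2]; nz <- dim(data)[3]
  voxel <- if (!is.null(meta$voxel)) meta$voxel else c(1, 1, 1)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(nx, ny, nz, 2, 0, 0, 0, nx, ny, nz))
  wf(c(nx * voxel[3], ny * voxel[2], nz * voxel[1]) * 10)  # cell in Angstrom
  wf(c(90, 90, 90))
  wi(c(1, 2, 3))
  wf(c(min(data), max(data), mean(data)))
  wi(c(0, 0))                       # ispg, nsymbt
  wi(rep(0, 25))                    # extra
  wf(c(0, 0, 0))                    # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  wf(stats::sd(data))
  label <- if (is.null(meta)) "" else
    paste0("phicao:", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  label <- strtrim(label, 800)
  wi(if (nzchar(label)) ceiling(nchar(label) / 80) else 0)
  lab <- charToRaw(label)
  writeBin(c(lab, raw(800 - length(lab))), con)
  for (p in seq_len(nz))
    writeBin(as.vector(t(data[, , p])), con, size = 4, endian = "little")
  invisible(path)
}

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_i <- readBin(con, "integer", 10, size = 4, endian = "little")
  nx <- hdr_i[1]; ny <- hdr_i[2]; nz <- hdr_i[3]; mode <- hdr_i[4]
  mx <- hdr_i[8]; my <- hdr_i[9]; mz <- hdr_i[10]
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  seek(con, 4 * 23)
  nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
  seek(con, 4 * 55)
  nlabl <- readBin(con, "integer", 1, size = 4, endian = "little")
  lab_raw <- readBin(con, "raw", 800)
  labels <- rawToChar(lab_raw[lab_raw != as.raw(0)])
  meta <- NULL
  m <- regmatches(labels, regexpr("phicao:\\{[^}]*\\}", labels))
  if (length(m) == 1)
    meta <- tryCatch(jsonlite::fromJSON(sub("^phicao:", "", m)),
                     error = function(e) NULL)
  seek(con, 1024 + nsymbt)
  n <- nx * ny * nz
  vals <- switch(as.character(mode),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "1" = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
    stop("unsupported MRC mode ", mode, call. = FALSE))
  arr <- array(0, dim = c(ny, nx, nz))
  for (p in seq_len(nz))
    arr[, , p] <- matrix(vals[((p - 1) * nx * ny + 1):(p * nx * ny)],
                         ny, nx, byrow = TRUE)
  voxel <- if (all(c(mx, my, mz) > 0) && all(cella > 0))
    c(cella[3] / mz, cella[2] / my, cella[1] / mx) / 10 else NULL
  list(data = arr, voxel = voxel, meta = meta)
}

#' Write an image stack to disk
#'
#' 32-bit-float multi-page TIFF (extension `.tif`/`.tiff`) or MRC mode-2
#' float (`.mrc`/`.dv`). The optical configuration travels in the TIFF
#' ImageDescription tag / first MRC label as JSON.
#'
#' @param stack an [image_stack()] (or `psf3d`)
#' @param path output path; format chosen by extension
#' @return the path, invisibly
#' @export
write_stack <- function(stack, path) {
  data <- if (inherits(stack, "psf3d")) stack$data else stack$data
  config <- stack$config
  meta <- config_metadata(config)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_tiff_float(data, path,
                     jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  } else if (ext %in% c("mrc", "dv")) {
    write_mrc(data, path, meta)
  } else stop("unsupported output format: .", ext, call. = FALSE)
  invisible(path)
}

#' Read an image stack
#'
#' Multi-page TIFF (any bit depth the `tiff` package reads; integer samples
#' are preserved exactly as floats) or MRC. Metadata found in the file is
#' used to build the [optical_config()]; arguments override file metadata
#' (with a warning when they disagree by more than 1%), and any required
#' field available from neither source raises an error naming it.
#'
#' @param path input file
#' @param na,wavelength,n_immersion,voxel,pupil_size,immersion_thickness
#'   metadata overrides (see [optical_config()])
#' @return an [image_stack()]
#' @export
read_stack <- function(path, na = NULL, wavelength = NULL, n_immersion = NULL,
                       voxel = NULL, pupil_size = NULL,
                       immersion_thickness = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  meta <- NULL
  if (ext %in% c("tif", "tiff")) {
    # as.is keeps integer samples unscaled; float images reject it
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
                      error = function(e)
                        tiff::readTIFF(path, all = TRUE, info = TRUE))
    if (!is.list(pages)) pages <- list(pages)
    d1 <- dim(pages[[1]])
    data <- array(0, dim = c(d1[1], d1[2], length(pages)))
    for (p in seq_along(pages)) data[, , p] <- as.numeric(pages[[p]])
    desc <- attr(pages[[1]], "description")
    if (!is.null(desc))
      meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
  } else if (ext %in% c("mrc", "dv")) {
    mrc <- read_mrc(path)
    data <- mrc$data
    meta <- mrc$meta
    if (is.null(meta$voxel) && !is.null(mrc$voxel)) meta$voxel <- mrc$voxel
  } else stop("unsupported input format: .", ext, call. = FALSE)
  pick <- function(name, override, scalar = TRUE) {
    filev <- meta[[name]]
    if (!is.null(override) && !is.null(filev) &&
        any(abs(as.numeric(override) - as.numeric(filev)) >
              0.01 * pmax(abs(as.numeric(filev)), 1e-12)))
      warning("override for `", name, "` differs from file metadata (",
              paste(signif(as.numeric(filev), 6), collapse = ","),
              "); using the override", call. = FALSE)
    if (!is.null(override)) override else filev
  }
  vals <- list(na = pick("na", na), wavelength = pick("wavelength", wavelength),
               n_immersion = pick("n_immersion", n_immersion),
               voxel = pick("voxel", voxel))
  missing <- names(vals)[vapply(vals, is.null, logical(1))]
  if (length(missing))
    stop("required metadata neither in file nor supplied: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ps <- pick("pupil_size", pupil_size)
  it <- pick("immersion_thickness", immersion_thickness)
  config <- optical_config(vals$na, vals$wavelength, vals$n_immersion,
                           voxel = vals$voxel,
                           shape = c(dim(data)[3], dim(data)[1], dim(data)[2]),
                           pupil_size = if (is.null(ps)) 512 else ps,
                           immersion_thickness =
                             if (is.null(it)) 1.5e5 else it)
  image_stack(data, config)
}

#' Write a measurement result
#'
#' JSON carrying the estimated spec (mode names, magnitudes, units), the
#' per-cycle estimates, the RMS wavefront traces and the metric samples;
#' [read_measurement()] restores the spec losslessly (full double precision).
#'
#' @param fit a `cao_fit` (or bare [aberration_spec()])
#' @param path output path
#' @return the path, invisibly
#' @export
write_measurement <- function(fit, path) {
  if (inherits(fit, "aberration_spec"))
    fit <- list(estimate = fit, per_cycle = NULL, rms_wavefront = numeric(0),
                rms_update = numeric(0), n_cycles = 0, objective = "none",
                traces = NULL)
  est <- fit$estimate
  out <- list(
    modes = as.list(stats::setNames(as.numeric(est), names(est))),
    units = as.list(stats::setNames(vapply(names(est), function(m) {
      if (m == "sa") "delta_n" else if (m %in% shift_modes) "nm" else "lambda"
    }, character(1)), names(est))),
    n_cycles = fit$n_cycles,
    objective = fit$objective,
    rms_wavefront_nm = fit$rms_wavefront,
    rms_update_nm = fit$rms_update,
    per_cycle = if (!is.null(fit$per_cycle))
      as.data.frame(fit$per_cycle) else NULL,
    traces = fit$traces)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a measurement result
#'
#' @param path a file written by [write_measurement()]
#' @return list with `spec` (an [aberration_spec()]) and the stored traces
#' @export
read_measurement <- function(path) {
  x <- jsonlite::fromJSON(path)
  mags <- unlist(x$modes)
  spec <- if (length(mags))
    aberration_spec(magnitudes = mags) else aberration_spec()
  list(spec = spec, units = x$units, n_cycles = x$n_cycles,
       objective = x$objective, rms_wavefront_nm = x$rms_wavefront_nm,
       rms_update_nm = x$rms_update_nm, per_cycle = x$per_cycle,
       traces = x$traces)
}
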