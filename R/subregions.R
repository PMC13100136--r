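# Spatially varying correction: aberrations measured in user-selected
# subregions, every voxel assigned to its nearest region, each region
# corrected inside an enclosing padded cuboid, and the corrected cubes
# merged through a hard mask partition.

#' Define a rectangular subregion
#'
#' Bounds are 0-based and half-open (`z0 <= z < z1` etc.), matching the
#' plain-text region-file convention `id z0 z1 y0 y1 x0 x1`.
#'
#' @param id integer region identifier
#' @param z0,z1,y0,y1,x0,x1 bounding box (0-based, half-open)
#' @return a `region`
#' @export
region <- function(id, z0, z1, y0, y1, x0, x1) {
  stopifnot(z1 > z0, y1 > y0, x1 > x0, z0 >= 0, y0 >= 0, x0 >= 0)
  structure(list(id = as.integer(id),
                 z = c(z0, z1), y = c(y0, y1), x = c(x0, x1)),
            class = "region")
}

#' Read a region table
#'
#' One region per line: `id z0 z1 y0 y1 x0 x1` (0-based, half-open);
#' lines starting with `#` are ignored.
#'
#' @param path file path
#' @return list of [region()]s
#' @export
read_regions <- function(path) {
  tab <- utils::read.table(path, col.names = c("id", "z0", "z1", "y0", "y1",
                                               "x0", "x1"))
  lapply(seq_len(nrow(tab)), function(i)
    region(tab$id[i], tab$z0[i], tab$z1[i], tab$y0[i], tab$y1[i],
           tab$x0[i], tab$x1[i]))
}

# squared distance (voxel or physical units) of every coordinate to a
# half-open interval [a, b) of voxel indices, for 1-based voxel centers
axis_dist <- function(n, a, b, scale = 1) {
  i <- seq_len(n)                 # 1-based; region voxels are a+1 .. b
  d <- pmax(0, (a + 1) - i, i - b)
  (d * scale)^2
}

#' Assign every voxel to its nearest subregion
#'
#' Voxels inside a region get its id; voxels outside get the id of the
#' region whose bounding box is nearest (Euclidean distance to the box, in
#' voxel units by default), ties broken by the lowest id.
#'
#' @param shape stack shape `c(nz, ny, nx)`
#' @param regions list of [region()]s
#' @param voxel optional `c(dz, dy, dx)` for physical-distance assignment
#' @return integer array `[ny, nx, nz]` of region ids
#' @export
assign_voxels <- function(shape, regions, voxel = NULL) {
  if (length(regions) == 0) stop("at least one region required", call. = FALSE)
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  sc <- if (is.null(voxel)) c(1, 1, 1) else voxel
  best_d <- array(Inf, dim = c(ny, nx, nz))
  labels <- array(NA_integer_, dim = c(ny, nx, nz))
  ord <- order(vapply(regions, function(r) r$id, integer(1)))
  for (r in regions[rev(ord)]) {  # lowest id written last wins ties
    if (r$z[2] > nz || r$y[2] > ny || r$x[2] > nx)
      stop("region ", r$id, " exceeds the stack bounds", call. = FALSE)
    dz <- axis_dist(nz, r$z[1], r$z[2], sc[1])
    dy <- axis_dist(ny, r$y[1], r$y[2], sc[2])
    dx <- axis_dist(nx, r$x[1], r$x[2], sc[3])
    d <- outer(outer(dy, dx, `+`), dz, `+`)
    upd <- d <= best_d
    best_d[upd] <- d[upd]
    labels[upd] <- r$id
  }
  labels
}

# next 5-smooth size >= n (FFT-friendly padding)
next_fft_size <- function(n) {
  repeat {
    m <- n
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(n)
    n <- n + 1
  }
}

# enclosing processing cuboid of a region: padded, FFT-friendly, clipped to
# the stack with edge replication where it overruns
region_cube <- function(r, shape, pad = 12) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  want <- function(a, b, n) {
    size <- min(next_fft_size(b - a + 2 * pad), n)
    lo <- max(1, min(a + 1 - pad, n - size + 1))
    c(lo, lo + size - 1)
  }
  list(z = want(r$z[1], r$z[2], nz), y = want(r$y[1], r$y[2], ny),
       x = want(r$x[1], r$x[2], nx))
}

#' Correct a stack with spatially varying aberrations
#'
#' Each region is expanded to the smallest FFT-friendly enclosing cuboid
#' (padded with surrounding stack content), corrected with its own
#' aberration spec via [correct_stack()], and only the voxels assigned to
#' that region ([assign_voxels()]) are copied into the output, producing a
#' hard-partition merge of the corrected cubes.
#'
#' @param stack an [image_stack()]
#' @param regions list of [region()]s
#' @param specs list of [aberration_spec()]s (or `cao_fit`s), one per region
#' @param params [correction_params()]
#' @param pad cube padding in voxels on each side; about half the PSF extent
#'   keeps the windowed deconvolution close to the full-field one
#' @return the corrected [image_stack()]
#' @export
correct_by_region <- function(stack, regions, specs,
                              params = correction_params(), pad = 12) {
  stopifnot(length(regions) == length(specs))
  config <- stack$config
  labels <- assign_voxels(config$shape, regions)
  out <- array(0, dim = dim(stack$data))
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    spec <- specs[[i]]
    if (inherits(spec, "cao_fit")) spec <- spec$estimate
    cube <- region_cube(r, config$shape, pad)
    sub <- stack$data[cube$y[1]:cube$y[2], cube$x[1]:cube$x[2],
                      cube$z[1]:cube$z[2], drop = FALSE]
    sub_cfg <- optical_config(config$na, config$wavelength,
                              config$n_immersion, voxel = config$voxel,
                              shape = c(dim(sub)[3], dim(sub)[1], dim(sub)[2]),
                              pupil_size = config$pupil_size,
                              immersion_thickness = config$immersion_thickness)
    corr <- correct_stack(image_stack(sub, sub_cfg), spec, params)
    sel <- labels[cube$y[1]:cube$y[2], cube$x[1]:cube$x[2],
                  cube$z[1]:cube$z[2], drop = FALSE] == r$id
    block <- out[cube$y[1]:cube$y[2], cube$x[1]:cube$x[2],
                 cube$z[1]:cube$z[2], drop = FALSE]
    block[sel] <- corr$data[sel]
    out[cube$y[1]:cube$y[2], cube$x[1]:cube$x[2],
        cube$z[1]:cube$z[2]] <- block
  }
  image_stack(out, config, background = stack$background)
}

#' Spatially varying correction of a raw SIM stack
#'
#' Small regions rarely support a reliable pattern-vector estimate, so each
#' region's spec drives a full-image reconstruction and the region masks
#' only restrict where each reconstruction contributes.
#'
#' @param raw a `sim_raw`
#' @param regions list of [region()]s
#' @param specs list of [aberration_spec()]s, one per region
#' @param ... passed to [reconstruct_sim()]
#' @return an [image_stack()]
#' @export
correct_by_region_sim <- function(raw, regions, specs, ...) {
  stopifnot(length(regions) == length(specs))
  labels <- assign_voxels(raw$config$shape, regions)
  out <- NULL
  for (i in seq_along(regions)) {
    spec <- specs[[i]]
    if (inherits(spec, "cao_fit")) spec <- spec$estimate
    rec <- reconstruct_sim(raw, spec = spec, ...)
    if (is.null(out)) out <- array(0, dim = dim(rec$data))
    sel <- labels == regions[[i]]$id
    out[sel] <- rec$data[sel]
  }
  image_stack(out, raw$config)
}
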