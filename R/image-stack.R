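#' 3D intensity stack with physical metadata
#'
#' @param data numeric array `[ny, nx, nz]` of intensities
#' @param config an [optical_config()] whose `shape` matches `data`
#' @param background optional scalar background offset already present in the
#'   data (recorded, not subtracted)
#' @return an object of class `image_stack`
#' @export
image_stack <- function(data, config, background = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!all(is.finite(data))) stop("stack intensities must be finite", call. = FALSE)
  d <- dim(data)
  if (!all(d == config$shape[c(2, 3, 1)]))
    stop(sprintf("data dims [%s] (y,x,z) do not match config shape [%s] (z,y,x)",
                 paste(d, collapse = ","),
                 paste(config$shape, collapse = ",")), call. = FALSE)
  structure(list(data = data, config = config, background = background),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d x %d (y,x,z), range [%.4g, %.4g]\n",
              d[1], d[2], d[3], min(x$data), max(x$data)))
  print(x$config)
  invisible(x)
}

as_image_stack <- function(x, config) {
  if (inherits(x, "image_stack")) x
  else if (inherits(x, "psf3d")) image_stack(x$data, x$config)
  else image_stack(x, config)
}

# median of the border voxels (one-voxel-thick faces of the volume)
border_median <- function(data) {
  d <- dim(data)
  stats::median(c(data[c(1, d[1]), , ], data[, c(1, d[2]), ],
                  data[, , c(1, d[3])]))
}

#' Subtract a border-median background estimate
#'
#' Estimates the background as the median over the one-voxel-thick border of
#' the stack, subtracts it and clips at zero. A DC-dominated spectrum
#' destabilizes the sharpness metric, so measurement applies this by default.
#'
#' @param stack an [image_stack()]
#' @return the background-subtracted `image_stack`
#' @export
subtract_background <- function(stack) {
  bg <- border_median(stack$data)
  image_stack(pmax(stack$data - bg, 0), stack$config, background = bg)
}
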