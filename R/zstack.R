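#' Construct a z-stack object
#'
#' A z-stack is a 3-D intensity grid (slice, row, col) with the objective
#' z-position of each slice, the substrate for all optical measurements.
#'
#' @param intensities 3-D numeric array `[slice, row, col]`, non-negative.
#' @param z_positions numeric vector of z-positions (micrometres), one per
#'   slice, strictly monotone. By convention z = 0 is the focus and negative
#'   values are below the sample.
#' @param pixel_size optional pixel size in micrometres per pixel.
#'
#' @return An object of class `zstack`.
#' @export
zstack <- function(intensities, z_positions, pixel_size = NULL) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("intensities must be a 3-D array [slice, row, col]")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (length(z_positions) != dim(intensities)[1L])
    stop("length(z_positions) must equal the number of slices")
  dz <- diff(z_positions)
  if (length(dz) && !(all(dz > 0) || all(dz < 0)))
    stop("z_positions must be strictly monotone")
  structure(
    list(intensities = intensities, z_positions = as.numeric(z_positions),
         pixel_size = pixel_size),
    class = "zstack"
  )
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("zstack: %d slices of %d x %d px, z in [%g, %g] um\n",
              d[1L], d[2L], d[3L], min(x$z_positions), max(x$z_positions)))
  invisible(x)
}

n_slices <- function(stack) dim(stack$intensities)[1L]

slice_matrix <- function(stack, i) stack$intensities[i, , ]

#' Write a z-stack as a multi-page TIFF with a JSON sidecar
#'
#' One 16-bit grayscale page per slice; the sidecar records z-positions and
#' pixel size so the stack round-trips losslessly.
#'
#' @param stack a [zstack()].
#' @param tiff_path output TIFF path.
#' @param sidecar_path output JSON path (default: `tiff_path` with `.json`).
#' @return Invisibly, the TIFF path.
#' @export
write_zstack <- function(stack, tiff_path,
                         sidecar_path = sub("\\.tiff?$", ".json", tiff_path)) {
  pages <- lapply(seq_len(n_slices(stack)),
                  function(i) slice_matrix(stack, i) / 65535)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(z_positions = stack$z_positions, pixel_size = stack$pixel_size),
    sidecar_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(tiff_path)
}

#' Read a z-stack written by [write_zstack()]
#'
#' @inheritParams write_zstack
#' @return A [zstack()] with integer-valued 16-bit intensities.
#' @export
read_zstack <- function(tiff_path,
                        sidecar_path = sub("\\.tiff?$", ".json", tiff_path)) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (i in seq_along(pages)) arr[i, , ] <- round(pages[[i]] * 65535)
  zstack(arr, side$z_positions, pixel_size = side$pixel_size)
}
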