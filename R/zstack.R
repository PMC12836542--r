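# Z-stack container and multi-page TIFF I/O.

#' Z-stack of grayscale planes
#'
#' One well/day acquisition: an ordered list of equally-shaped 2D grayscale
#' matrices (intensities in [0, 1]) plus the physical calibration.
#'
#' @param planes list of numeric matrices, all the same dimension.
#' @param pixel_size lateral calibration, um/pixel (> 0).
#' @param plane_spacing axial distance between planes, um.
#' @param well_id,day acquisition metadata.
#' @return an object of class \code{zstack}.
#' @export
zstack <- function(planes, pixel_size, plane_spacing = NA_real_,
                   well_id = NA_character_, day = NA_real_) {
  if (is.matrix(planes)) planes <- list(planes)
  if (length(planes) < 1L) stop("a zstack needs at least one plane")
  if (!all(vapply(planes, is.matrix, logical(1))))
    stop("planes must be 2D matrices")
  dims <- unique(lapply(planes, dim))
  if (length(dims) != 1L) stop("all planes must share the same shape")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  structure(list(planes = planes, pixel_size = pixel_size,
                 plane_spacing = plane_spacing, well_id = well_id, day = day),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("zstack: %d plane(s) of %d x %d px, %.3g um/px (well %s, day %s)\n",
              length(x$planes), d[1], d[2], x$pixel_size,
              x$well_id, format(x$day)))
  invisible(x)
}

#' Read a multi-page grayscale TIFF as a Z-stack
#'
#' @param path TIFF file, one page per Z-plane; 8/16-bit integer or float
#'   pages are mapped to [0, 1] by the reader.
#' @param pixel_size um/pixel calibration to attach.
#' @param plane_spacing,well_id,day metadata to attach.
#' @return a [zstack()].
#' @export
read_zstack <- function(path, pixel_size, plane_spacing = NA_real_,
                        well_id = NA_character_, day = NA_real_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse accidental RGB
    p
  })
  zstack(pages, pixel_size = pixel_size, plane_spacing = plane_spacing,
         well_id = well_id, day = day)
}

#' Write a Z-stack as a 16-bit multi-page TIFF
#'
#' @param stack a [zstack()]; intensities are clipped to [0, 1].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_zstack <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  planes <- lapply(stack$planes,
                   function(p) matrix(pmin(1, pmax(0, p)), nrow(p), ncol(p)))
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  invisible(path)
}
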