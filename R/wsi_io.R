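#' @useDynLib gnnsurv, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm median rbinom rexp rnorm runif sd setNames
#' @importFrom utils read.csv write.csv head modifyList
#' @importFrom graphics plot
#' @importFrom grDevices colorRamp
NULL

# structured condition helper used throughout the package
gs_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "gnnsurv_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' Open a slide image
#'
#' Reads a plain raster (PNG, single-image TIFF) or a pyramidal multi-page
#' TIFF and returns a handle describing its resolution pyramid. Plain
#' rasters are first-class inputs: the whole test suite runs on them, no
#' proprietary slide format is required. Raster files carry no
#' magnification metadata, so the acquisition magnification must be
#' supplied via `base_magnification` (typically 40 for slides digitised at
#' x40, 0.25 um/pixel).
#'
#' @param path path to a PNG or (possibly multi-page pyramidal) TIFF file.
#' @param base_magnification objective magnification of the highest
#'   resolution level, e.g. `40`. Required when the file carries no
#'   magnification metadata (always the case for PNG/TIFF fixtures).
#' @param mpp optional microns per pixel at the base level.
#' @return An object of class `slide_handle` with fields `path`,
#'   `base_magnification`, `levels` (data frame of `downsample`, `width`,
#'   `height`), `mpp` and the decoded pixel data.
#' @seealso [read_region()]
#' @export
open_slide <- function(path, base_magnification = NULL, mpp = NULL) {
  if (!file.exists(path)) {
    gs_error(sprintf("slide file does not exist: %s", path), "format_error")
  }
  ext <- tolower(tools::file_ext(path))
  imgs <- switch(ext,
    png = list(png::readPNG(path)),
    tif = ,
    tiff = {
      x <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(x)) list(x) else x
    },
    gs_error(sprintf("unsupported slide format '%s' (expect png/tif/tiff)", ext),
             "format_error")
  )
  imgs <- lapply(imgs, as_rgb_array)
  if (is.null(base_magnification)) {
    gs_error(paste0("no magnification metadata available for '", path,
                    "'; supply base_magnification (config key base_magnification)"),
             "configuration_error")
  }
  w0 <- ncol(imgs[[1]]); h0 <- nrow(imgs[[1]])
  ds <- vapply(imgs, function(im) w0 / ncol(im), numeric(1))
  ord <- order(ds)
  imgs <- imgs[ord]; ds <- ds[ord]
  if (ds[1] != 1 || any(diff(ds) <= 0)) {
    gs_error("pyramid levels must have strictly increasing downsample factors",
             "format_error")
  }
  # heights must be consistent with the downsample factor within rounding
  hs <- vapply(imgs, nrow, integer(1))
  if (any(abs(hs - h0 / ds) > 1)) {
    gs_error("pyramid level heights inconsistent with downsample factors",
             "format_error")
  }
  structure(list(
    path = path,
    base_magnification = as.numeric(base_magnification),
    levels = data.frame(downsample = ds,
                        width = vapply(imgs, ncol, integer(1)),
                        height = hs),
    mpp = mpp,
    images = imgs
  ), class = "slide_handle")
}

#' @export
print.slide_handle <- function(x, ...) {
  cat(sprintf("<slide_handle> %s\n", x$path))
  cat(sprintf("  base magnification: x%g%s\n", x$base_magnification,
              if (!is.null(x$mpp)) sprintf(" (%g um/px)", x$mpp) else ""))
  cat(sprintf("  levels: %s\n", paste(sprintf("x%g (%dx%d)",
              x$levels$downsample, x$levels$width, x$levels$height),
              collapse = ", ")))
  invisible(x)
}

# decode whatever readPNG/readTIFF produced into an integer 0..255 H x W x 3
as_rgb_array <- function(im) {
  if (is.matrix(im)) im <- array(rep(im, 3L), c(dim(im), 3L))
  if (dim(im)[3] > 3L) im <- im[, , 1:3, drop = FALSE]
  if (dim(im)[3] != 3L) gs_error("image must have 3 channels", "format_error")
  storage.mode(im) <- "double"
  if (max(im) <= 1) im <- im * 255
  array(as.integer(round(im)), dim(im))
}

#' Construct a raster image
#'
#' Lightweight container for an 8-bit RGB tile: the pixel array, the
#' magnification it was read at, and its origin in level-0 pixel
#' coordinates (0-based).
#'
#' @param pixels H x W x 3 integer array with values in 0..255.
#' @param magnification magnification the pixels correspond to.
#' @param origin length-2 integer vector, level-0 (x, y) of the top-left
#'   corner.
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(pixels, magnification, origin = c(0L, 0L)) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L || d[1] < 1L || d[2] < 1L) {
    gs_error("pixels must be a H x W x 3 array with H, W >= 1", "format_error")
  }
  structure(list(pixels = pixels, magnification = as.numeric(magnification),
                 origin = as.integer(origin)),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image> %dx%d px at x%g, origin (%d, %d)\n",
              d[2], d[1], x$magnification, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Read a rectangular region of a slide at a requested magnification
#'
#' The bounding box is given in level-0, 0-based, half-open pixel
#' coordinates (this convention is used for all public bounding boxes in
#' the package). The region is read from the finest pyramid level whose
#' downsample does not exceed the requested factor and resized by exact
#' area averaging (box filter), so downsampling a constant image is exact
#' and the operation is fully deterministic. The output size is the
#' box size divided by `base_magnification / magnification`, rounded down.
#'
#' @param handle a [open_slide()] handle.
#' @param magnification requested magnification, at most the base.
#' @param bbox length-4 numeric `(x, y, w, h)` in level-0 pixels.
#' @return A [raster_image()] at the requested magnification.
#' @export
read_region <- function(handle, magnification, bbox) {
  stopifnot(inherits(handle, "slide_handle"), length(bbox) == 4)
  if (magnification > handle$base_magnification) {
    gs_error("requested magnification exceeds base magnification", "bounds_error")
  }
  factor <- handle$base_magnification / magnification
  x <- bbox[1]; y <- bbox[2]; w <- bbox[3]; h <- bbox[4]
  W0 <- handle$levels$width[1]; H0 <- handle$levels$height[1]
  if (x < 0 || y < 0 || w <= 0 || h <= 0 || x + w > W0 || y + h > H0) {
    gs_error(sprintf("bbox (%g,%g,%g,%g) outside slide bounds %dx%d",
                     x, y, w, h, W0, H0), "bounds_error")
  }
  out_w <- floor(w / factor); out_h <- floor(h / factor)
  if (out_w < 1 || out_h < 1) gs_error("requested region smaller than one pixel",
                                       "bounds_error")
  # nearest finer (or equal) level
  lev <- max(which(handle$levels$downsample <= factor + 1e-9))
  ds <- handle$levels$downsample[lev]
  im <- handle$images[[lev]]
  rows <- (floor(y / ds) + 1L):min(ceiling((y + h) / ds), nrow(im))
  cols <- (floor(x / ds) + 1L):min(ceiling((x + w) / ds), ncol(im))
  tile <- im[rows, cols, , drop = FALSE]
  out <- resize_area(tile, out_h, out_w)
  raster_image(out, magnification, origin = c(as.integer(x), as.integer(y)))
}

# Exact box-filter (area average) resize of an H x W x 3 integer array.
# Each output pixel averages the input area it covers, with fractional
# boundary pixels weighted by overlap.
resize_area <- function(im, out_h, out_w) {
  d <- dim(im)
  L <- box_weights(d[1], out_h)
  R <- box_weights(d[2], out_w)
  out <- array(0, c(out_h, out_w, 3L))
  for (ch in 1:3) out[, , ch] <- L %*% im[, , ch] %*% t(R)
  array(as.integer(pmin(255, pmax(0, round(out)))), dim(out))
}

# out_n x in_n row-stochastic overlap weights of the box filter
box_weights <- function(in_n, out_n) {
  if (in_n == out_n) return(diag(in_n))
  s <- in_n / out_n
  W <- matrix(0, out_n, in_n)
  for (i in seq_len(out_n)) {
    a <- (i - 1) * s; b <- i * s
    lo <- floor(a) + 1L; hi <- min(ceiling(b), in_n)
    for (j in lo:hi) {
      W[i, j] <- min(b, j) - max(a, j - 1)
    }
  }
  W / s
}

#' Write a raster image or mask as PNG
#'
#' @param x a [raster_image()], a logical mask matrix, or an H x W x 3
#'   array in 0..255.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  if (inherits(x, "raster_image")) x <- x$pixels
  if (is.logical(x)) x <- matrix(as.numeric(x), nrow(x), ncol(x))
  else x <- x / 255
  png::writePNG(x, path)
  invisible(path)
}
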