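#' Tissue-mask parameters
#'
#' Parameter bundle for [compute_tissue_mask()]. Defaults implement the
#' standard low-magnification cleanup: median smoothing of the saturation
#' channel (kernel 7), Otsu binarisation, morphological closing with a
#' 4x4 square kernel, removal of components below 100 px (area defined at
#' the x5 segmentation level), and hole handling where only holes larger
#' than 16 px are preserved as tissue cavities, at most 8 per component.
#'
#' @param median_kernel odd median filter kernel size in pixels.
#' @param close_kernel side of the square closing structuring element.
#' @param min_area_px minimum component area, in pixels at
#'   `reference_magnification`.
#' @param min_hole_px holes with area at most this many pixels are filled.
#' @param max_holes maximum number of preserved holes per component.
#' @param reference_magnification magnification at which `min_area_px` is
#'   defined (the segmentation level, x5).
#' @return An object of class `mask_params`.
#' @export
mask_params <- function(median_kernel = 7L, close_kernel = 4L,
                        min_area_px = 100L, min_hole_px = 16L,
                        max_holes = 8L, reference_magnification = 5) {
  stopifnot(median_kernel >= 1, median_kernel %% 2 == 1,
            close_kernel >= 0, min_area_px >= 0, min_hole_px >= 0,
            max_holes >= 0, reference_magnification > 0)
  structure(list(median_kernel = as.integer(median_kernel),
                 close_kernel = as.integer(close_kernel),
                 min_area_px = as.numeric(min_area_px),
                 min_hole_px = as.numeric(min_hole_px),
                 max_holes = as.integer(max_holes),
                 reference_magnification = reference_magnification),
            class = "mask_params")
}

#' Saturation channel of an RGB image
#'
#' Standard RGB to HSV conversion, returning only the saturation channel:
#' `S = (max - min) / max`, defined as 0 where `max = 0`. Stained tissue is
#' strongly saturated while background glass is near-white (S close to 0),
#' which is what makes saturation the natural channel for tissue
#' segmentation.
#'
#' @param image a [raster_image()] or an H x W x 3 array in 0..255.
#' @return H x W numeric matrix with values in `[0, 1]`.
#' @export
saturation_channel <- function(image) {
  px <- if (inherits(image, "raster_image")) image$pixels else image
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  s <- (mx - mn) / mx
  s[mx == 0] <- 0
  s
}

#' Label connected components of a binary mask
#'
#' Scanline-ordered labelling with selectable connectivity. The package
#' convention is 8-connectivity for tissue components and 4-connectivity
#' for holes (the standard duality that avoids checkerboard ambiguity).
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of the same shape; 0 is background, components
#'   are numbered from 1 in scanline order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  .label_components_cpp(mask, as.integer(connectivity))
}

#' Compute a binary tissue mask from a low-magnification RGB image
#'
#' Pipeline, in order: median-filter the saturation channel, Otsu
#' threshold (foreground is the high-saturation side), morphological
#' closing with a square kernel, removal of small connected components
#' (8-connectivity; the area threshold is scaled by
#' `(magnification / reference)^2` when the mask is computed away from the
#' reference segmentation level), then per-component hole handling
#' (4-connectivity): every interior hole is filled except holes larger
#' than `min_hole_px`, of which at most `max_holes` largest are preserved
#' as tissue cavities (ties broken by larger area, then scanline order).
#'
#' An image with no tissue after filtering yields an empty mask with a
#' warning, not an error.
#'
#' @param image a [raster_image()] (its magnification is used for area
#'   scaling) or an H x W x 3 array.
#' @param params a [mask_params()] bundle.
#' @param scale_to_level0 optional linear factor from mask pixels to
#'   level-0 pixels, stored on the result for downstream rendering.
#' @return An object of class `tissue_mask` with fields `mask` (logical
#'   H x W), `magnification` and `scale_to_level0`.
#' @export
compute_tissue_mask <- function(image, params = mask_params(),
                                scale_to_level0 = NULL) {
  mag <- if (inherits(image, "raster_image")) image$magnification else
    params$reference_magnification
  s <- saturation_channel(image)
  if (params$median_kernel > 1) {
    s <- EBImage::medianFilter(s, size = params$median_kernel %/% 2L)
  }
  thr <- EBImage::otsu(EBImage::Image(s), range = c(0, 1), levels = 256)
  fg <- s > thr
  if (params$close_kernel > 1) {
    kern <- matrix(1, params$close_kernel, params$close_kernel)
    fg <- EBImage::closing(fg * 1, kern) > 0.5
  }
  min_area <- params$min_area_px * (mag / params$reference_magnification)^2
  mask <- clean_mask(fg, min_area, params$min_hole_px, params$max_holes)
  if (!any(mask)) {
    warning("tissue mask is empty after filtering", call. = FALSE)
  }
  structure(list(mask = mask, magnification = mag,
                 scale_to_level0 = scale_to_level0),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %dx%d at x%g, %.1f%% tissue\n",
              ncol(x$mask), nrow(x$mask), x$magnification,
              100 * mean(x$mask)))
  invisible(x)
}

# component/hole cleanup; idempotent by construction
clean_mask <- function(fg, min_area, min_hole, max_holes) {
  lab <- label_components(fg, 8L)
  if (max(lab) > 0) {
    areas <- tabulate(lab)
    drop <- which(areas < min_area)
    if (length(drop)) {
      fg <- fg & !(lab %in% drop)
      lab <- label_components(fg, 8L)
    }
  }
  if (!any(fg)) return(fg)
  # holes: background components (4-conn) not touching the image border
  bg <- label_components(!fg, 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- setdiff(border, 0L)
  hole_ids <- setdiff(seq_len(max(bg, 0L)), border)
  if (!length(hole_ids)) return(fg)
  hole_area <- tabulate(bg)[hole_ids]
  # owner component: component label adjacent (4-neighbourhood) to the hole
  owner <- vapply(hole_ids, function(h) {
    idx <- which(bg == h, arr.ind = TRUE)
    nb <- rbind(cbind(idx[, 1] - 1L, idx[, 2]), cbind(idx[, 1] + 1L, idx[, 2]),
                cbind(idx[, 1], idx[, 2] - 1L), cbind(idx[, 1], idx[, 2] + 1L))
    keep <- nb[, 1] >= 1 & nb[, 1] <= nrow(bg) & nb[, 2] >= 1 & nb[, 2] <= ncol(bg)
    labs <- lab[nb[keep, , drop = FALSE]]
    labs <- labs[labs > 0]
    if (length(labs)) labs[1] else 0L
  }, integer(1))
  fill <- logical(length(hole_ids))
  for (comp in unique(owner)) {
    in_comp <- which(owner == comp)
    big <- in_comp[hole_area[in_comp] > min_hole]
    # keep at most max_holes largest; ties by area then scanline (label) order
    keep <- big[order(-hole_area[big], hole_ids[big])][seq_len(min(length(big), max_holes))]
    fill[setdiff(in_comp, keep)] <- TRUE
  }
  if (any(fill)) fg[bg %in% hole_ids[fill]] <- TRUE
  fg
}
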