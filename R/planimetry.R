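#' TTC-stained slice image
#'
#' Wraps an RGB raster of one transverse heart slice after TTC staining
#' (viable myocardium red, infarct white/ivory) together with its
#' identifiers.
#'
#' @param pixels Numeric array `height x width x 3`, values in `[0, 1]`.
#' @param heart_id,slice_index Labels.
#' @param scale_mm_px Optional physical scale in mm per pixel.
#' @return An object of class `slice_image`.
#' @export
slice_image <- function(pixels, heart_id = "heart", slice_index = 1L,
                        scale_mm_px = NULL) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L,
            all(is.finite(pixels)))
  if (prod(dim(pixels)[1:2]) == 0L) stop("empty raster")
  if (!is.null(scale_mm_px) && scale_mm_px <= 0)
    stop("scale_mm_px must be positive")
  structure(list(pixels = pixels, heart_id = heart_id,
                 slice_index = slice_index, scale_mm_px = scale_mm_px),
            class = "slice_image")
}

#' Read a slice image from a PNG file
#'
#' @param path PNG path.
#' @inheritParams slice_image
#' @return A [slice_image()].
#' @export
read_slice_image <- function(path, heart_id = "heart", slice_index = 1L,
                             scale_mm_px = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  slice_image(px, heart_id, slice_index, scale_mm_px)
}

#' Write a slice image to PNG
#' @param slice A [slice_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_slice_image <- function(slice, path) {
  stopifnot(inherits(slice, "slice_image"))
  png::writePNG(slice$pixels, path)
  invisible(path)
}

#' Segment tissue from background
#'
#' Classifies pixels as tissue when their RGB distance from the
#' background colour exceeds a threshold, keeps the largest connected
#' component, and (by default) excludes enclosed lumen holes from the
#' tissue area. The background colour is estimated as the median colour
#' of the image border unless given.
#'
#' @param slice A [slice_image()].
#' @param bg_color Length-3 RGB background colour, or `NULL` to estimate
#'   from the border.
#' @param bg_dist Minimum RGB (Euclidean) distance from the background
#'   colour for a pixel to count as tissue (default 0.15).
#' @param exclude_lumen Keep enclosed holes (ventricular lumen) out of
#'   the tissue mask (default `TRUE`); with `FALSE` holes are filled in.
#' @return Logical matrix, `TRUE` for tissue pixels.
#' @export
segment_tissue <- function(slice, bg_color = NULL, bg_dist = 0.15,
                           exclude_lumen = TRUE) {
  stopifnot(inherits(slice, "slice_image"))
  px <- slice$pixels
  d <- dim(px)
  if (is.null(bg_color)) {
    border <- rbind(px[1, , ], px[d[1], , ], px[, 1, ], px[, d[2], ])
    bg_color <- apply(border, 2, stats::median)
  }
  dist2 <- (px[, , 1] - bg_color[1])^2 + (px[, , 2] - bg_color[2])^2 +
    (px[, , 3] - bg_color[3])^2
  mask <- dist2 > bg_dist^2
  if (!any(mask)) stop("no tissue detected")
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  if (!exclude_lumen) {
    mask <- EBImage::fillHull(mask) > 0
  }
  mask
}

#' Segment infarcted (white/ivory) tissue
#'
#' Within the tissue mask, classifies pixels as infarct when they are
#' pale: low saturation and high value in HSV colour space. Viable
#' TTC-stained myocardium is saturated red and fails both cuts. Zero
#' infarct is a valid outcome.
#'
#' @param slice A [slice_image()].
#' @param tissue Logical tissue mask from [segment_tissue()].
#' @param s_max Maximum saturation for infarct (default 0.35).
#' @param v_min Minimum value/brightness for infarct (default 0.6).
#' @return Logical matrix, `TRUE` for infarcted pixels (subset of tissue).
#' @export
segment_infarct <- function(slice, tissue, s_max = 0.35, v_min = 0.6) {
  stopifnot(inherits(slice, "slice_image"), is.logical(tissue))
  if (!any(tissue)) stop("tissue mask is empty")
  px <- slice$pixels
  idx <- which(tissue)
  npx <- prod(dim(px)[1:2])
  rgb <- rbind(px[, , 1][idx], px[, , 2][idx], px[, , 3][idx])
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  infarct <- matrix(FALSE, dim(px)[1], dim(px)[2])
  infarct[idx] <- hsv["s", ] < s_max & hsv["v", ] > v_min
  infarct
}

#' Planimetry of one slice
#'
#' Runs tissue and infarct segmentation and reports pixel areas and the
#' infarct fraction for a single slice. An optional manual exclusion
#' mask (e.g. papillary-muscle artifacts) removes pixels from both
#' areas.
#'
#' @param slice A [slice_image()].
#' @param exclude Optional logical matrix of pixels to drop.
#' @param ... Passed to [segment_tissue()] and [segment_infarct()]
#'   (matched by name).
#' @return An object of class `planimetry_result`: list with
#'   `heart_id`, `slice_index`, `tissue_area_px`, `infarct_area_px`,
#'   `infarct_fraction_pct`.
#' @export
planimetry_slice <- function(slice, exclude = NULL, ...) {
  dots <- list(...)
  tiss_args <- dots[names(dots) %in% names(formals(segment_tissue))]
  inf_args <- dots[names(dots) %in% names(formals(segment_infarct))]
  tissue <- do.call(segment_tissue, c(list(slice), tiss_args))
  infarct <- do.call(segment_infarct, c(list(slice, tissue), inf_args))
  if (!is.null(exclude)) {
    tissue <- tissue & !exclude
    infarct <- infarct & !exclude
    if (!any(tissue)) stop("no tissue left after exclusion")
  }
  structure(list(heart_id = slice$heart_id,
                 slice_index = slice$slice_index,
                 tissue_area_px = sum(tissue),
                 infarct_area_px = sum(infarct),
                 infarct_fraction_pct = 100 * sum(infarct) / sum(tissue)),
            class = "planimetry_result")
}

#' Heart-level infarct fraction
#'
#' Pools slice-level areas into one per-heart infarct fraction,
#' `100 * sum(infarct) / sum(tissue)` (area-weighted pooling; larger
#' slices count more). The unweighted mean of per-slice fractions is
#' reported alongside.
#'
#' @param slices List of [planimetry_slice()] results from one heart.
#' @return List with `pooled_pct` (primary), `slice_mean_pct`,
#'   `tissue_area_px`, `infarct_area_px`, `n_slices`.
#' @export
infarct_fraction <- function(slices) {
  stopifnot(length(slices) >= 1L,
            all(vapply(slices, inherits, logical(1), "planimetry_result")))
  tiss <- sum(vapply(slices, `[[`, numeric(1), "tissue_area_px"))
  inf <- sum(vapply(slices, `[[`, numeric(1), "infarct_area_px"))
  if (tiss == 0) stop("zero total tissue area")
  list(pooled_pct = 100 * inf / tiss,
       slice_mean_pct = mean(vapply(slices, `[[`, numeric(1),
                                    "infarct_fraction_pct")),
       tissue_area_px = tiss, infarct_area_px = inf,
       n_slices = length(slices))
}

#' Rescale a slice image by an integer-agnostic factor
#'
#' Nearest-neighbour rescaling, used to check scale invariance of the
#' planimetry chain.
#'
#' @param slice A [slice_image()].
#' @param factor Linear scale factor (> 0).
#' @return A rescaled [slice_image()].
#' @export
rescale_slice <- function(slice, factor) {
  stopifnot(inherits(slice, "slice_image"), factor > 0)
  d <- dim(slice$pixels)
  h2 <- max(1L, round(d[1] * factor))
  w2 <- max(1L, round(d[2] * factor))
  ri <- round(seq(1, d[1], length.out = h2))
  ci <- round(seq(1, d[2], length.out = w2))
  slice_image(slice$pixels[ri, ci, , drop = FALSE],
              slice$heart_id, slice$slice_index, slice$scale_mm_px)
}
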