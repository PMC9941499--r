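#' Nuclear segmentation parameters
#'
#' The nuclear-marker channel is segmented per timeframe on its maximum
#' z-projection: median filter, bandpass (difference of Gaussians with SDs
#' derived from the pixel size cuts as `cut / 2.355`, i.e. FWHM-matched),
#' Otsu binarisation, then marker-based splitting of touching nuclei on the
#' distance transform with regions bounded by the Voronoi partition of the
#' markers.  TF-channel stacks additionally filter objects to an area range
#' before extending the 2D mask into a 3D z-prism.
#'
#' @param bandpass_low_px lower size cut in pixels (structures below are
#'   treated as noise).
#' @param bandpass_high_px upper size cut in pixels.
#' @param tf_min_area_px,tf_max_area_px inclusive area bounds (pixels) for
#'   objects kept by [segment_tf_stack()].
#' @param median_radius_px radius of the despeckling median filter
#'   (0 disables it).
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(bandpass_low_px = 5, bandpass_high_px = 25,
                                tf_min_area_px = 50, tf_max_area_px = 200,
                                median_radius_px = 1) {
  assert_scalar_num(bandpass_low_px, "bandpass_low_px", 1e-6)
  assert_scalar_num(bandpass_high_px, "bandpass_high_px", bandpass_low_px)
  if (bandpass_low_px >= bandpass_high_px)
    stop("bandpass_low_px must be < bandpass_high_px", call. = FALSE)
  assert_scalar_num(tf_min_area_px, "tf_min_area_px", 1)
  assert_scalar_num(tf_max_area_px, "tf_max_area_px", tf_min_area_px)
  assert_scalar_num(median_radius_px, "median_radius_px", 0, integer = TRUE)
  structure(list(bandpass_low_px = bandpass_low_px,
                 bandpass_high_px = bandpass_high_px,
                 tf_min_area_px = tf_min_area_px,
                 tf_max_area_px = tf_max_area_px,
                 median_radius_px = as.integer(median_radius_px)),
            class = "segmentation_config")
}

## Local maxima of a distance map with a minimum mutual separation.
## Returns a matrix (y, x) of kept peak pixels, deterministically ordered.
distmap_markers <- function(dist, mask, min_sep) {
  brush_size <- 2L * max(1L, floor(min_sep)) + 1L
  dil <- EBImage::dilate(EBImage::Image(dist),
                         EBImage::makeBrush(brush_size, shape = "disc"))
  is_peak <- mask & (abs(dist - as_mat(dil)) < 1e-9) & (dist > 0)
  idx <- which(is_peak, arr.ind = TRUE)
  if (!nrow(idx)) return(idx)
  v <- dist[idx]
  ord <- order(-v, idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  kept <- matrix(numeric(0), 0L, 2L)
  min_d2 <- min_sep^2
  for (k in seq_len(nrow(idx))) {
    p <- idx[k, ]
    if (!nrow(kept) ||
        all((kept[, 1L] - p[1L])^2 + (kept[, 2L] - p[2L])^2 >= min_d2)) {
      kept <- rbind(kept, p)
    }
  }
  unname(kept)
}

#' Segment nuclei in a single (projected) timeframe
#'
#' Median filter, difference-of-Gaussians bandpass, Otsu threshold, then
#' splitting of touching nuclei: markers are the local maxima of the
#' Euclidean distance transform (minimum separation `bandpass_high_px / 2`)
#' and each foreground pixel is assigned to its nearest marker by
#' geodesic-distance growth, i.e. the Voronoi partition of the markers
#' restricted to the foreground mask.
#'
#' A near-constant image (intensity range below machine tolerance) yields an
#' empty mask with a warning rather than an error.
#'
#' @param image 2D numeric intensity matrix (a per-frame maximum projection).
#' @param config a [segmentation_config()].
#' @return an integer label matrix of the same shape (0 = background).
#' @export
segment_frame <- function(image, config = segmentation_config()) {
  stopifnot(is.matrix(image), inherits(config, "segmentation_config"))
  if (!all(is.finite(image))) stop("image contains non-finite values",
                                   call. = FALSE)
  empty <- matrix(0L, nrow(image), ncol(image))
  rng <- range(image)
  if (diff(rng) <= max(1e-12, 1e-9 * max(abs(rng)))) {
    warning("near-constant image; returning empty mask")
    return(empty)
  }
  x <- (image - rng[1L]) / diff(rng)
  img <- EBImage::Image(x)
  if (config$median_radius_px > 0)
    img <- EBImage::medianFilter(img, config$median_radius_px)
  s_lo <- config$bandpass_low_px / 2.355
  s_hi <- config$bandpass_high_px / 2.355
  ## Gaussian kernel radius clamped so the filter fits small images
  rad <- function(s) min(2L * as.integer(ceiling(3 * s)) + 1L,
                         2L * ((min(dim(image)) - 1L) %/% 2L) + 1L)
  band <- as_mat(EBImage::gblur(img, sigma = s_lo, radius = rad(s_lo))) -
          as_mat(EBImage::gblur(img, sigma = s_hi, radius = rad(s_hi)))
  brng <- range(band)
  if (diff(brng) <= 1e-12) {
    warning("bandpassed image is constant; returning empty mask")
    return(empty)
  }
  b <- (band - brng[1L]) / diff(brng)
  thr <- EBImage::otsu(EBImage::Image(b), range = c(0, 1))
  mask <- b > thr
  if (!any(mask)) return(empty)
  dist <- as_mat(EBImage::distmap(EBImage::Image(mask)))
  markers <- distmap_markers(dist, mask, config$bandpass_high_px / 2)
  if (!nrow(markers)) return(empty)
  seeds <- matrix(0L, nrow(image), ncol(image))
  seeds[markers] <- seq_len(nrow(markers))
  ## large lambda => growth metric is dominated by spatial distance, giving
  ## the Voronoi partition of the markers within the mask
  lab <- EBImage::propagate(EBImage::Image(dist), EBImage::Image(seeds),
                            mask = EBImage::Image(mask), lambda = 1e4)
  out <- matrix(as.integer(EBImage::imageData(lab)), nrow(image), ncol(image))
  storage.mode(out) <- "integer"
  out
}

#' Filter labelled regions by area
#'
#' Keeps regions whose pixel area lies in `[min_area, max_area]` (both
#' bounds inclusive) and relabels the survivors consecutively in order of
#' their original label.  Idempotent.
#'
#' @param labels integer label matrix.
#' @param min_area,max_area inclusive pixel-area bounds.
#' @return relabelled integer matrix.
#' @export
filter_labels_by_area <- function(labels, min_area, max_area) {
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) return(labels)
  areas <- tabulate(labels, nbins = max(ids))[ids]
  keep <- ids[areas >= min_area & areas <= max_area]
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (k in seq_along(keep)) out[labels == keep[k]] <- k
  out
}

#' Segment nuclei in a single-timepoint TF-channel stack
#'
#' Segments the maximum z-projection with [segment_frame()], keeps objects
#' with area within `[tf_min_area_px, tf_max_area_px]` (inclusive), and
#' extends the 2D mask across all z-slices to form a 3D prism region per
#' nucleus.
#'
#' @param stack numeric `Z x Y x X` array (TF channel).
#' @param config a [segmentation_config()].
#' @return list with `labels` (filtered 2D label matrix), `labels3d`
#'   (`Z x Y x X` integer array, the z-prism extension) and `n_z`.
#' @export
segment_tf_stack <- function(stack, config = segmentation_config()) {
  stopifnot(length(dim(stack)) == 3L)
  nz <- dim(stack)[1L]
  proj <- stack[1L, , ]
  if (nz > 1L) for (z in 2:nz) proj <- pmax(proj, stack[z, , ])
  lab2d <- segment_frame(proj, config)
  lab2d <- filter_labels_by_area(lab2d, config$tf_min_area_px,
                                 config$tf_max_area_px)
  lab3d <- aperm(array(lab2d, dim = c(dim(lab2d), nz)), c(3L, 1L, 2L))
  list(labels = lab2d, labels3d = lab3d, n_z = nz)
}

#' Voxel coordinates of one nucleus's 3D prism region
#'
#' @param labels 2D integer label matrix.
#' @param n_z number of z-slices.
#' @param id region label.
#' @return integer matrix with columns `z`, `y`, `x`.
#' @export
label_region_3d <- function(labels, n_z, id) {
  px <- which(labels == id, arr.ind = TRUE)
  if (!nrow(px)) stop("label ", id, " not present", call. = FALSE)
  out <- cbind(z = rep(seq_len(n_z), each = nrow(px)),
               y = rep(px[, 1L], n_z), x = rep(px[, 2L], n_z))
  storage.mode(out) <- "integer"
  out
}
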