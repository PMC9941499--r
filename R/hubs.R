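#' Select the top fraction of nuclei by integrated spot signal
#'
#' Keeps the nuclei whose integrated MS2/PP7 signal is at or above the
#' `(1 - fraction)` quantile, i.e. the top `fraction` of the cohort (top
#' 15%, 5%, 50%, ...).  Ties at the cutoff are all retained, so the count
#' may exceed `ceiling(fraction * n)`.
#'
#' @param signal numeric vector of integrated signal, one value per nucleus.
#' @param fraction fraction to keep, in `(0, 1]`.
#' @return integer indices of the retained nuclei (ascending).
#' @export
select_top_sites <- function(signal, fraction) {
  if (!length(signal)) stop("no nuclei to select from", call. = FALSE)
  assert_scalar_num(fraction, "fraction", 1e-12, 1)
  k <- ceiling(fraction * length(signal))
  thr <- sort(signal, decreasing = TRUE)[k]
  which(signal >= thr)
}

#' Extract a TF-channel patch centred on a transcription site
#'
#' Locates the brightest spot-channel voxel within a nucleus's 3D region
#' (ties broken by ascending z, y, x) and extracts the `side_px x side_px`
#' TF-channel patch centred on it, on that single z-plane.  A patch that
#' would extend beyond the image is skipped (returns `NULL` with a message).
#'
#' @param tf_stack numeric `Z x Y x X` TF-channel array.
#' @param spot_stack numeric `Z x Y x X` spot-channel array.
#' @param region3d integer matrix `(z, y, x)` of the nucleus's voxels (see
#'   [label_region_3d()]).
#' @param side_px odd patch side in pixels (29 or 41 in typical use).
#' @return object of class `enrichment_patch`: list with `values`
#'   (`side x side` matrix), `center` `(z, y, x)`, `site_kind`; or `NULL`.
#' @export
extract_patch <- function(tf_stack, spot_stack, region3d, side_px = 29L) {
  stopifnot(length(dim(tf_stack)) == 3L, side_px %% 2L == 1L)
  region3d <- as.matrix(region3d)
  if (!nrow(region3d)) stop("empty nucleus region", call. = FALSE)
  v <- spot_stack[region3d]
  ord <- order(-v, region3d[, 1L], region3d[, 2L], region3d[, 3L])[1L]
  ctr <- region3d[ord, ]
  patch_at(tf_stack, ctr, side_px, "transcription_site")
}

patch_at <- function(tf_stack, ctr, side_px, kind) {
  h <- (side_px - 1L) %/% 2L
  d <- dim(tf_stack)
  if (ctr[2L] - h < 1L || ctr[2L] + h > d[2L] ||
      ctr[3L] - h < 1L || ctr[3L] + h > d[3L]) {
    message("patch at (", paste(ctr, collapse = ","),
            ") exceeds image bounds; site skipped")
    return(NULL)
  }
  vals <- tf_stack[ctr[1L], (ctr[2L] - h):(ctr[2L] + h),
                   (ctr[3L] - h):(ctr[3L] + h)]
  structure(list(values = vals, center = unname(ctr), site_kind = kind),
            class = "enrichment_patch")
}

#' Extract a random-site control patch
#'
#' Draws a centre uniformly from the nucleus's segmented pixels on the given
#' z-plane (the same plane as the transcription site) and extracts the TF
#' patch there.  Re-draws up to `max_tries` times if the patch would leave
#' the image; returns `NULL` if no in-bounds candidate is found.
#'
#' @param tf_stack numeric `Z x Y x X` TF-channel array.
#' @param region3d integer matrix `(z, y, x)` of the nucleus's voxels.
#' @param z_plane z-slice on which to sample.
#' @param side_px odd patch side.
#' @param max_tries bounded number of redraws.
#' @return an `enrichment_patch` (site_kind `"random_site"`) or `NULL`.
#' @export
sample_random_site <- function(tf_stack, region3d, z_plane, side_px = 29L,
                               max_tries = 100L) {
  region3d <- as.matrix(region3d)
  cand <- region3d[region3d[, 1L] == z_plane, , drop = FALSE]
  if (!nrow(cand)) stop("region has no pixels on z-plane ", z_plane,
                        call. = FALSE)
  for (i in seq_len(max_tries)) {
    ctr <- cand[sample.int(nrow(cand), 1L), ]
    p <- suppressMessages(patch_at(tf_stack, ctr, side_px, "random_site"))
    if (!is.null(p)) return(p)
  }
  message("no in-bounds random site after ", max_tries, " tries; skipped")
  NULL
}

## Integer radial bin of every pixel of a side x side patch: Euclidean
## distance from the centre pixel, rounded half-up ("a pixel increment").
radial_bins <- function(side) {
  c0 <- (side + 1L) / 2
  d <- sqrt(outer((seq_len(side) - c0)^2, (seq_len(side) - c0)^2, `+`))
  bins <- floor(d + 0.5)
  storage.mode(bins) <- "integer"
  bins
}

## Per-bin means of one patch, ordered by bin 0..max.
patch_bin_means <- function(values, bins) {
  vapply(split(as.numeric(values), as.integer(bins)), mean, numeric(1))
}

#' Radial enrichment profile and mean heatmap of a set of patches
#'
#' Pixels are grouped into bins by integer-rounded Euclidean distance from
#' the patch centre (bin 0 is the centre pixel alone).  Each site's bin
#' means are divided by that site's endmost *complete* bin — the last bin
#' inside the inscribed circle, radius `(side - 1) / 2` — so the endmost
#' complete bin's mean relative enrichment is exactly 1.  Bins beyond the
#' inscribed radius (patch corners) are reported but flagged incomplete.
#' The SEM is computed across the per-site bin means, and the heatmap is the
#' pixel-wise mean of the per-site normalised patches.
#'
#' @param patches list of `enrichment_patch` objects of a uniform side
#'   (`NULL` entries are dropped).
#' @return list with `profile` (data.frame `bin`,
#'   `mean_relative_enrichment`, `sem`, `n_pixels`, `n_sites`, `complete`)
#'   and `heatmap` (side x side matrix).
#' @export
radial_enrichment <- function(patches) {
  patches <- Filter(Negate(is.null), patches)
  if (!length(patches)) stop("no patches", call. = FALSE)
  side <- nrow(patches[[1L]]$values)
  for (p in patches) if (nrow(p$values) != side)
    stop("patches must share one side length", call. = FALSE)
  bins <- radial_bins(side)
  r_end <- (side - 1L) %/% 2L
  norm <- lapply(patches, function(p) {
    mb <- patch_bin_means(p$values, bins)
    ref <- mb[[as.character(r_end)]]
    list(bin_means = mb / ref, patch = p$values / ref)
  })
  mat <- do.call(rbind, lapply(norm, `[[`, "bin_means"))
  bin_ids <- as.integer(colnames(mat))
  n_pix <- tabulate(bins + 1L)[bin_ids + 1L]
  profile <- data.frame(
    bin = bin_ids,
    mean_relative_enrichment = colMeans(mat),
    sem = apply(mat, 2L, function(v)
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0),
    n_pixels = n_pix,
    n_sites = nrow(mat),
    complete = bin_ids <= r_end)
  rownames(profile) <- NULL
  heatmap <- Reduce(`+`, lapply(norm, `[[`, "patch")) / length(norm)
  list(profile = profile, heatmap = heatmap)
}

#' Per-site radial curve areas
#'
#' For each site, the area of its normalised radial curve above the flat
#' profile: sum over complete bins of (relative enrichment - 1).
#'
#' @param patches list of `enrichment_patch` objects.
#' @return numeric vector, one area per site.
#' @export
site_profile_areas <- function(patches) {
  patches <- Filter(Negate(is.null), patches)
  if (!length(patches)) stop("no patches", call. = FALSE)
  side <- nrow(patches[[1L]]$values)
  bins <- radial_bins(side)
  r_end <- (side - 1L) %/% 2L
  vapply(patches, function(p) {
    mb <- patch_bin_means(p$values, bins)
    mb <- mb / mb[[as.character(r_end)]]
    keep <- as.integer(names(mb)) <= r_end
    sum(mb[keep] - 1)
  }, numeric(1))
}

#' Compare radial-curve areas between two conditions
#'
#' Two-sided Wilcoxon rank-sum test between the per-site curve areas of two
#' conditions (see [site_profile_areas()]).
#'
#' @param patches_a,patches_b lists of `enrichment_patch` objects.
#' @return list with `p_value`, `areas_a`, `areas_b`.
#' @export
compare_profile_areas <- function(patches_a, patches_b) {
  a <- site_profile_areas(patches_a)
  b <- site_profile_areas(patches_b)
  res <- compare_groups(a, b)
  list(p_value = res$p_value, areas_a = a, areas_b = b)
}
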