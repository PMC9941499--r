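#' Spot signal of one nucleus in one projected frame
#'
#' Finds the brightest pixel within the nucleus region (ties broken in
#' row-major order: lowest row, then lowest column), sums the intensities of
#' the 5x5 pixel window centred on it, and subtracts the region's median
#' intensity times the number of window pixels as background.  Window pixels
#' outside the region but inside the image are included; when the window
#' extends beyond the image it is cropped and the background multiplier is
#' the actual number of window pixels.  The result may be negative before
#' baseline zeroing.
#'
#' @param projected_frame 2D intensity matrix (maximum z-projection).
#' @param region two-column integer matrix of region pixels `(y, x)`.
#' @param window_px odd window side length (default 5).
#' @return list with `intensity` and `spot_yx = c(y, x)`.
#' @export
extract_spot_signal <- function(projected_frame, region, window_px = 5L) {
  stopifnot(is.matrix(projected_frame))
  region <- as.matrix(region)
  if (nrow(region) < 1L) stop("region must contain at least 1 pixel",
                              call. = FALSE)
  if (window_px %% 2L != 1L) stop("window_px must be odd", call. = FALSE)
  vals <- projected_frame[region]
  k <- argmax_rowmajor(vals, region[, 1L], region[, 2L])
  sy <- region[k, 1L]; sx <- region[k, 2L]
  h <- (window_px - 1L) %/% 2L
  rows <- max(1L, sy - h):min(nrow(projected_frame), sy + h)
  cols <- max(1L, sx - h):min(ncol(projected_frame), sx + h)
  wsum <- sum(projected_frame[rows, cols])
  n_w <- length(rows) * length(cols)
  list(intensity = wsum - n_w * stats::median(vals),
       spot_yx = unname(c(sy, sx)))
}

#' Extract per-nucleus spot traces from a movie
#'
#' For every valid lineage, measures the spot signal of the chosen channel
#' in each frame's maximum projection with [extract_spot_signal()] using the
#' nucleus's segmented region, then zeroes the baseline by subtracting each
#' trajectory's minimum.
#'
#' @param stack an `image_stack` (see [simulate_movie()]).
#' @param masks list of per-frame label matrices matching `tracks`.
#' @param tracks a `nucleus_tracks` data.frame; only valid rows are used.
#' @param channel channel name (`"ms2"` or `"pp7"`).
#' @return data.frame of class `spot_traces`: `lineage_id`, `channel`,
#'   `frame`, `raw`, `baseline_zeroed`, `spot_y`, `spot_x`.  Within every
#'   trace `min(baseline_zeroed)` is exactly 0.
#' @export
build_traces <- function(stack, masks, tracks, channel = c("ms2", "pp7")) {
  channel <- match.arg(channel)
  tr <- valid_tracks(tracks)
  if (!nrow(tr))
    return(structure(data.frame(lineage_id = integer(), channel = character(),
                                frame = integer(), raw = numeric(),
                                baseline_zeroed = numeric(),
                                spot_y = integer(), spot_x = integer()),
                     class = c("spot_traces", "data.frame")))
  n_frames_movie <- dim(stack$channels[[channel]])[1L]
  if (max(tr$frame) > n_frames_movie || length(masks) < max(tr$frame))
    stop("tracks refer to frames beyond the movie/mask range", call. = FALSE)
  ## per-frame projections and label pixel lookups
  frames_needed <- sort(unique(tr$frame))
  proj <- list(); regions <- list()
  for (t in frames_needed) {
    proj[[t]] <- max_project(stack, channel, t)
    lab <- masks[[t]]
    px <- which(lab > 0L)
    regions[[t]] <- split(px, lab[px])
  }
  ny <- nrow(masks[[1L]])
  out <- lapply(split(tr, tr$lineage_id), function(g) {
    g <- g[order(g$frame), ]
    raw <- numeric(nrow(g)); sy <- integer(nrow(g)); sx <- integer(nrow(g))
    for (k in seq_len(nrow(g))) {
      t <- g$frame[k]
      lin <- regions[[t]][[as.character(g$label[k])]]
      if (is.null(lin)) stop("label ", g$label[k], " missing in frame ", t,
                             call. = FALSE)
      region <- cbind(((lin - 1L) %% ny) + 1L, ((lin - 1L) %/% ny) + 1L)
      s <- extract_spot_signal(proj[[t]], region)
      raw[k] <- s$intensity; sy[k] <- s$spot_yx[1L]; sx[k] <- s$spot_yx[2L]
    }
    data.frame(lineage_id = g$lineage_id[1L], channel = channel,
               frame = g$frame, raw = raw,
               baseline_zeroed = raw - min(raw), spot_y = sy, spot_x = sx)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("spot_traces", "data.frame")
  out
}
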