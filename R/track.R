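#' Region properties of a label mask
#'
#' Centroid, area, major-axis length (from the second moments of the pixel
#' coordinates, `4 * sqrt(largest eigenvalue)` as for the standard image
#' ellipse) and whether the region touches the image border.
#'
#' @param labels integer label matrix.
#' @return data.frame with columns `label`, `y`, `x`, `area`,
#'   `major_axis`, `touches_edge`.
#' @export
mask_centroids <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  ny <- nrow(labels); nx <- ncol(labels)
  out <- lapply(ids, function(id) {
    px <- which(labels == id, arr.ind = TRUE)
    y <- px[, 1L]; x <- px[, 2L]
    cy <- mean(y); cx <- mean(x)
    cyy <- mean((y - cy)^2); cxx <- mean((x - cx)^2)
    cyx <- mean((y - cy) * (x - cx))
    tr <- cyy + cxx
    det <- cyy * cxx - cyx^2
    lmax <- tr / 2 + sqrt(pmax(0, tr^2 / 4 - det))
    data.frame(label = id, y = cy, x = cx, area = nrow(px),
               major_axis = 4 * sqrt(lmax),
               touches_edge = any(y == 1L | y == ny | x == 1L | x == nx))
  })
  if (!length(out))
    return(data.frame(label = integer(), y = numeric(), x = numeric(),
                      area = integer(), major_axis = numeric(),
                      touches_edge = logical()))
  do.call(rbind, out)
}

#' Link segmented nuclei across frames into lineages
#'
#' Between consecutive frames, each nucleus is matched to the previous-frame
#' nucleus minimising the Euclidean centroid distance, greedily in ascending
#' distance order with one-to-one matching (ties broken by previous then
#' current label).  Unmatched detections start new lineages; lineages with no
#' match in a frame terminate there (no gap closing).
#'
#' @param masks list of integer label matrices, one per frame, equal shape.
#' @return data.frame of class `nucleus_tracks`, one row per nucleus-frame:
#'   `lineage_id`, `frame`, `label`, `y`, `x`, `area`, `major_axis`,
#'   `touches_edge`, `valid` (all `TRUE`; see [apply_exclusions()]),
#'   `exclusion_reason`.
#' @export
link_frames <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  shp <- dim(masks[[1L]])
  for (m in masks) if (!identical(dim(m), shp))
    stop("all masks must share the same shape", call. = FALSE)
  props <- lapply(masks, mask_centroids)
  rows <- list()
  next_lineage <- 1L
  prev_assign <- integer(0)  # lineage id per row of props[[t-1]]
  for (t in seq_along(props)) {
    cur <- props[[t]]
    n_cur <- nrow(cur)
    assign_cur <- rep(NA_integer_, n_cur)
    prev <- if (t > 1L) props[[t - 1L]] else NULL
    if (n_cur && !is.null(prev) && nrow(prev) && length(prev_assign)) {
      live <- which(!is.na(prev_assign))
      if (length(live)) {
        pairs <- expand.grid(i = live, j = seq_len(n_cur))
        pairs$d <- sqrt((prev$y[pairs$i] - cur$y[pairs$j])^2 +
                        (prev$x[pairs$i] - cur$x[pairs$j])^2)
        pairs <- pairs[order(pairs$d, prev$label[pairs$i],
                             cur$label[pairs$j]), , drop = FALSE]
        used_prev <- logical(nrow(prev)); used_cur <- logical(n_cur)
        for (k in seq_len(nrow(pairs))) {
          i <- pairs$i[k]; j <- pairs$j[k]
          if (!used_prev[i] && !used_cur[j]) {
            used_prev[i] <- TRUE; used_cur[j] <- TRUE
            assign_cur[j] <- prev_assign[i]
          }
        }
      }
    }
    for (j in seq_len(n_cur)) {
      if (is.na(assign_cur[j])) {
        assign_cur[j] <- next_lineage
        next_lineage <- next_lineage + 1L
      }
    }
    if (n_cur)
      rows[[t]] <- cbind(data.frame(lineage_id = assign_cur, frame = t), cur)
    prev_assign <- assign_cur
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lineage_id = integer(), frame = integer(), label = integer(),
               y = numeric(), x = numeric(), area = integer(),
               major_axis = numeric(), touches_edge = logical())
  out$valid <- TRUE
  out$exclusion_reason <- "none"
  out <- out[order(out$lineage_id, out$frame), ]
  rownames(out) <- NULL
  class(out) <- c("nucleus_tracks", "data.frame")
  out
}

#' Apply lineage exclusion rules
#'
#' A whole lineage is marked invalid when its region touches the image
#' border in any frame (`edge_contact`) or when its centroid moves, between
#' two consecutive frames, strictly more than the nucleus length — the
#' major-axis length of the region in the earlier frame
#' (`jump_exceeds_length`).  A displacement exactly equal to the length is
#' retained.
#'
#' @param tracks a `nucleus_tracks` data.frame from [link_frames()].
#' @return the tracks with `valid`/`exclusion_reason` updated.
#' @export
apply_exclusions <- function(tracks) {
  stopifnot(inherits(tracks, "nucleus_tracks") || is.data.frame(tracks))
  tracks$valid <- TRUE
  tracks$exclusion_reason <- "none"
  for (id in unique(tracks$lineage_id)) {
    ix <- which(tracks$lineage_id == id)
    tr <- tracks[ix, ]
    tr <- tr[order(tr$frame), ]
    reason <- NULL
    if (any(tr$touches_edge)) {
      reason <- "edge_contact"
    } else if (nrow(tr) > 1L) {
      d <- sqrt(diff(tr$y)^2 + diff(tr$x)^2)
      if (any(d > tr$major_axis[-nrow(tr)])) reason <- "jump_exceeds_length"
    }
    if (!is.null(reason)) {
      tracks$valid[ix] <- FALSE
      tracks$exclusion_reason[ix] <- reason
    }
  }
  tracks
}

#' Keep only valid lineages
#'
#' @param tracks a `nucleus_tracks` data.frame.
#' @return the subset of rows with `valid == TRUE`.
#' @export
valid_tracks <- function(tracks) {
  out <- tracks[tracks$valid, , drop = FALSE]
  rownames(out) <- NULL
  out
}
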