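#' Write an image stack as a multi-page TIFF
#'
#' Pages are ordered channel-major, then frame, then z (C, T, Z), each page
#' a `Y x X` plane, so the file holds the full `T x Z x Y x X x C` data.
#' Intensities are scaled into `[0, 1]` by the global maximum and written
#' as 32-bit samples; the scale is returned so values can be restored.
#'
#' @param stack an `image_stack` (see [simulate_movie()]).
#' @param path output file path.
#' @return invisibly, the intensity scale (global maximum).
#' @export
write_image_stack <- function(stack, path) {
  pages <- list()
  sc <- max(vapply(stack$channels, max, numeric(1)), 1e-12)
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    d <- dim(a)
    for (t in seq_len(d[1L])) for (z in seq_len(d[2L]))
      pages[[length(pages) + 1L]] <- pmax(a[t, z, , ], 0) / sc
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(sc)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path.
#' @param dims integer `(T, Z)` page layout.
#' @param channels channel names in written order.
#' @param scale intensity scale returned by the writer.
#' @return an `image_stack`.
#' @export
read_image_stack <- function(path, dims, channels, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  tf <- dims[1L]; nz <- dims[2L]
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  out <- list()
  k <- 0L
  for (ch in channels) {
    a <- array(0, dim = c(tf, nz, ny, nx))
    for (t in seq_len(tf)) for (z in seq_len(nz)) {
      k <- k + 1L
      a[t, z, , ] <- pages[[k]] * scale
    }
    out[[ch]] <- a
  }
  structure(list(channels = out, pixel_size_um = NA_real_, spec = NULL),
            class = "image_stack")
}

#' Write a BED6 file (0-based half-open)
#'
#' @param df BED6-style data.frame (`chrom`, `start`, `end`, `name`,
#'   `score`, `strand`).
#' @param path output path (conventionally `.bed`).
#' @export
write_bed6 <- function(df, path) {
  df <- validate_intervals(df, "interval")
  gr <- granges0(df)
  names(gr) <- df$name
  S4Vectors::mcols(gr)$score <- df$score
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED file into a 0-based half-open interval table
#'
#' @param path BED file path.
#' @return BED6-style data.frame.
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  nm <- gr$name
  if (is.null(nm)) nm <- sprintf("interval_%d", seq_along(gr))
  sc <- gr$score
  if (is.null(sc)) sc <- 0L
  sc[is.na(sc)] <- 0L
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = nm, score = sc, strand = strand,
             stringsAsFactors = FALSE)
}
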