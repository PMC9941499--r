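#' Validate a BED6-style interval table
#'
#' Checks `0 <= start < end` and `strand` in `{+, -, .}`; reports the first
#' offending row number.  All coordinates in this package are 0-based
#' half-open, the BED convention.
#'
#' @param df data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param what label used in error messages.
#' @return the validated data.frame (invisibly completed with defaults).
#' @export
validate_intervals <- function(df, what = "interval") {
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(df)))
    stop(what, " table must have columns chrom, start, end", call. = FALSE)
  if (!"name" %in% names(df)) df$name <- sprintf("%s_%d", what, seq_len(nrow(df)))
  if (!"score" %in% names(df)) df$score <- 0L
  if (!"strand" %in% names(df)) df$strand <- "."
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop(sprintf("%s parse error at line %d: need 0 <= start < end", what,
                 bad[1L]), call. = FALSE)
  bad <- which(!df$strand %in% c("+", "-", "."))
  if (length(bad))
    stop(sprintf("%s parse error at line %d: bad strand '%s'", what, bad[1L],
                 df$strand[bad[1L]]), call. = FALSE)
  df
}

## 0-based half-open BED data.frame -> GRanges (1-based closed).
granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = ifelse(df$strand == ".", "*", df$strand))
}

#' Remove reads near exonic sequence
#'
#' Drops every read whose interval overlaps any exon expanded by
#' `margin_bp` on both sides (>= 1 bp overlap, strand-blind); a read whose
#' end exactly abuts the expanded exon boundary (half-open touch) is
#' retained.  Idempotent.
#'
#' @param reads,exons BED6-style data.frames (0-based half-open).
#' @param margin_bp exclusion margin around exons (default 50).
#' @return the retained rows of `reads`.
#' @export
filter_exonic_reads <- function(reads, exons, margin_bp = 50L) {
  reads <- validate_intervals(reads, "read")
  exons <- validate_intervals(exons, "exon")
  if (!nrow(reads) || !nrow(exons)) return(reads)
  exp_ex <- exons
  exp_ex$start <- pmax(0L, exons$start - margin_bp)
  exp_ex$end <- exons$end + margin_bp
  hit <- IRanges::overlapsAny(granges0(reads), granges0(exp_ex),
                              ignore.strand = TRUE)
  out <- reads[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score enhancer transcription from CAGE-style reads
#'
#' Counts reads overlapping each enhancer (>= 1 bp, strand-blind) before
#' and after the exon-proximity filter, and normalises the filtered count
#' to the enhancer size: `tss_score = filtered_count` per kb of enhancer.
#'
#' @param reads BED6-style read table.
#' @param enhancers BED6-style enhancer table.
#' @param exons optional exon table; when supplied, reads are filtered with
#'   [filter_exonic_reads()] before the filtered count.  When `NULL` the
#'   reads are assumed already filtered (filtered == raw).
#' @param margin_bp exon margin passed to the filter.
#' @return data.frame: `chrom`, `start`, `end`, `name`, `raw_count`,
#'   `filtered_count`, `tss_score` (reads per kb).
#' @export
score_enhancers <- function(reads, enhancers, exons = NULL, margin_bp = 50L) {
  reads <- validate_intervals(reads, "read")
  enhancers <- validate_intervals(enhancers, "enhancer")
  filt <- if (is.null(exons)) reads else
    filter_exonic_reads(reads, exons, margin_bp)
  enh_gr <- granges0(enhancers)
  raw <- if (nrow(reads))
    GenomicRanges::countOverlaps(enh_gr, granges0(reads),
                                 ignore.strand = TRUE) else
    integer(nrow(enhancers))
  fc <- if (nrow(filt))
    GenomicRanges::countOverlaps(enh_gr, granges0(filt),
                                 ignore.strand = TRUE) else
    integer(nrow(enhancers))
  data.frame(chrom = enhancers$chrom, start = enhancers$start,
             end = enhancers$end, name = enhancers$name,
             raw_count = as.integer(raw), filtered_count = as.integer(fc),
             tss_score = fc / ((enhancers$end - enhancers$start) / 1000),
             stringsAsFactors = FALSE)
}

#' Flag transcribed enhancers and the cumulative score curve
#'
#' An enhancer is transcribed when `tss_score >= threshold_score`; with a
#' threshold of exactly 0 the comparison is strict (`> 0`) so that
#' zero-score enhancers are never called transcribed.  Also returns the
#' cumulative-fraction curve of the scores (monotone, ending at 1).
#'
#' @param records data.frame from [score_enhancers()].
#' @param threshold_score transcribed-enhancer threshold (>= 0; an analysis
#'   choice, supplied explicitly).
#' @return list with `records` (input plus `transcribed`) and `cumulative`
#'   (data.frame `tss_score`, `cum_fraction`).
#' @export
call_transcribed <- function(records, threshold_score) {
  assert_scalar_num(threshold_score, "threshold_score", 0)
  records$transcribed <- if (threshold_score == 0)
    records$tss_score > 0 else records$tss_score >= threshold_score
  s <- sort(records$tss_score)
  cumulative <- data.frame(tss_score = s,
                           cum_fraction = seq_along(s) / length(s))
  list(records = records, cumulative = cumulative)
}

## Midpoint of a 0-based half-open interval.
interval_mid <- function(start, end) floor((start + end) / 2)

#' Classify enhancers by TSS orientation relative to TF-binding sites
#'
#' TF-binding sites are assigned to enhancers by >= 1 bp overlap.  For each
#' site, stranded TSS peaks whose midpoint lies within `window_bp` of the
#' site midpoint are collected; a TSS is *inward* when its transcription
#' proceeds toward the site (plus-strand TSS left of the site midpoint, or
#' minus-strand TSS right of it; a TSS overlapping the site itself counts
#' as inward) and *outward* otherwise.  Unstranded (`.`) peaks are skipped
#' with a warning.  Per enhancer: inward TSS(s) only gives `"inward"`,
#' outward only gives `"outward"`, both kinds give `"both"`, no in-window
#' TSS gives `"none"`.
#'
#' @param enhancers,tf_sites,tss_peaks BED6-style data.frames.
#' @param window_bp assignment window around the site midpoint (default
#'   500).
#' @return data.frame: `name` (enhancer), `orientation_class`,
#'   `n_inward`, `n_outward`.
#' @export
classify_tss_orientation <- function(enhancers, tf_sites, tss_peaks,
                                     window_bp = 500L) {
  enhancers <- validate_intervals(enhancers, "enhancer")
  tf_sites <- validate_intervals(tf_sites, "tf_site")
  tss_peaks <- validate_intervals(tss_peaks, "tss_peak")
  unstranded <- tss_peaks$strand == "."
  if (any(unstranded)) {
    warning(sum(unstranded), " TSS peak(s) without strand skipped")
    tss_peaks <- tss_peaks[!unstranded, , drop = FALSE]
  }
  ## site -> enhancer assignment by overlap
  hits <- GenomicRanges::findOverlaps(granges0(tf_sites), granges0(enhancers),
                                      ignore.strand = TRUE)
  n_in <- integer(nrow(enhancers)); n_out <- integer(nrow(enhancers))
  if (nrow(tss_peaks)) {
    site_mid <- interval_mid(tf_sites$start, tf_sites$end)
    tss_mid <- interval_mid(tss_peaks$start, tss_peaks$end)
    ## site-midpoint windows vs TSS midpoints, as ranges on each chromosome
    win_gr <- GenomicRanges::GRanges(
      tf_sites$chrom,
      IRanges::IRanges(start = pmax(0L, site_mid - window_bp) + 1L,
                       end = site_mid + window_bp + 1L))
    mid_gr <- GenomicRanges::GRanges(
      tss_peaks$chrom,
      IRanges::IRanges(start = tss_mid + 1L, width = 1L))
    wh <- GenomicRanges::findOverlaps(win_gr, mid_gr, ignore.strand = TRUE)
    for (k in seq_along(wh)) {
      si <- S4Vectors::queryHits(wh)[k]
      pi <- S4Vectors::subjectHits(wh)[k]
      if (abs(tss_mid[pi] - site_mid[si]) > window_bp) next
      overlaps_site <- tss_peaks$start[pi] < tf_sites$end[si] &&
        tf_sites$start[si] < tss_peaks$end[pi]
      inward <- overlaps_site ||
        (tss_mid[pi] < site_mid[si] && tss_peaks$strand[pi] == "+") ||
        (tss_mid[pi] > site_mid[si] && tss_peaks$strand[pi] == "-") ||
        (tss_mid[pi] == site_mid[si])
      enh_ix <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == si]
      for (e in enh_ix) {
        if (inward) n_in[e] <- n_in[e] + 1L else n_out[e] <- n_out[e] + 1L
      }
    }
  }
  cls <- ifelse(n_in > 0L & n_out > 0L, "both",
         ifelse(n_in > 0L, "inward",
         ifelse(n_out > 0L, "outward", "none")))
  data.frame(name = enhancers$name, orientation_class = cls,
             n_inward = n_in, n_outward = n_out, stringsAsFactors = FALSE)
}
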