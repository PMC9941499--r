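## BED6-style data.frame constructor (0-based half-open coordinates).
bed6 <- function(chrom, start, end, name, score = 0L, strand = ".") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
              name = name, score = score, strand = strand,
              stringsAsFactors = FALSE)
}

#' Simulate a toy genome fixture with known ground truth
#'
#' Builds BED-compatible interval sets on a synthetic chromosome (`chrS`)
#' for testing the enhancer TSS-score and orientation analyses: enhancers,
#' exons (some overlapping enhancer edges), stranded CAGE-style reads
#' (reads placed > 50 bp from every exon, plus decoy reads near exons and
#' intergenic background reads), TF-binding sites inside the enhancers, and
#' stranded TSS peaks placed so that each enhancer has a known
#' inward/outward orientation class.  Every enhancer's true filtered read
#' count, TSS score and orientation class are recorded by construction.
#'
#' Each enhancer occupies its own 10-kb territory so that windows never
#' reach a neighbouring enhancer's annotation.  Orientation classes cycle
#' through inward / outward / both / none; "none" enhancers additionally
#' carry an unstranded (`.`) decoy peak, which classifiers must skip.
#'
#' @param n_enhancers number of enhancers (>= 1).
#' @param seed integer seed; the fixture is bit-reproducible.
#' @param exon_margin_bp exon exclusion margin the fixture is built around.
#' @param window_bp TSS-to-site assignment window the fixture is built
#'   around.
#' @return list of BED6 data.frames `enhancers`, `exons`, `reads`,
#'   `tf_sites`, `tss_peaks`, and `ground_truth` (data.frame `name`,
#'   `raw_count`, `filtered_count`, `tss_score`, `orientation_class`).
#' @export
simulate_genome_fixture <- function(n_enhancers, seed = 1L,
                                    exon_margin_bp = 50L, window_bp = 500L) {
  assert_scalar_num(n_enhancers, "n_enhancers", 1, integer = TRUE)
  assert_scalar_num(seed, "seed", integer = TRUE)
  with_seed(seed, simulate_genome_fixture_impl(n_enhancers, exon_margin_bp,
                                               window_bp))
}

simulate_genome_fixture_impl <- function(n_enhancers, margin, window) {
  classes <- rep(c("inward", "outward", "both", "none"),
                 length.out = n_enhancers)
  enh <- list(); exons <- list(); reads <- list()
  tf_sites <- list(); peaks <- list(); gt <- list()
  read_id <- 0L
  mk_read <- function(start, width, name_prefix) {
    read_id <<- read_id + 1L
    bed6("chrS", start, start + width,
         sprintf("%s_%d", name_prefix, read_id), 0L,
         sample(c("+", "-"), 1L))
  }
  for (i in seq_len(n_enhancers)) {
    i0 <- (i - 1L) * 10000L + 1000L
    enh_len <- sample(600:2000, 1L)
    enh_start <- i0 + sample(2000:4000, 1L)
    enh_end <- enh_start + enh_len
    ename <- sprintf("enh_%03d", i)
    enh[[i]] <- bed6("chrS", enh_start, enh_end, ename, 0L, ".")

    ## exon either overlapping the enhancer head or well upstream
    exon_inside <- stats::runif(1) < 0.5
    if (exon_inside) {
      ex <- c(enh_start, enh_start + 100L)
    } else {
      ex <- c(enh_start - 1500L, enh_start - 1300L)
    }
    exons[[i]] <- bed6("chrS", ex[1L], ex[2L], sprintf("exon_%03d", i))

    ## clean reads: fully inside the enhancer, > margin from the exon
    safe_lo <- if (exon_inside) ex[2L] + margin else enh_start
    n_clean <- stats::rpois(1L, 2.5)
    for (k in seq_len(n_clean)) {
      w <- sample(1:25, 1L)
      s <- sample(safe_lo:(enh_end - w), 1L)
      reads[[length(reads) + 1L]] <- mk_read(s, w, "read")
    }
    ## decoy reads overlapping the (expanded) exon: removed by the filter
    for (k in seq_len(stats::rpois(1L, 1))) {
      w <- sample(5:15, 1L)
      s <- sample((ex[1L] - 30L):(ex[2L] + 20L - w), 1L)
      reads[[length(reads) + 1L]] <- mk_read(s, w, "exonic")
    }
    ## intergenic background reads: on no enhancer, far from exons
    for (k in seq_len(stats::rpois(1L, 1))) {
      w <- sample(1:25, 1L)
      s <- sample((i0 + 7000L):(i0 + 8500L - w), 1L)
      reads[[length(reads) + 1L]] <- mk_read(s, w, "bg")
    }

    ## TF sites inside the enhancer
    n_sites <- sample(1:2, 1L)
    site_mids <- sort(sample(seq(enh_start + 60L, enh_end - 60L), n_sites))
    if (n_sites == 2L && diff(site_mids) < 120L) {
      n_sites <- 1L
      site_mids <- site_mids[1L]
    }
    for (k in seq_len(n_sites)) {
      tf_sites[[length(tf_sites) + 1L]] <-
        bed6("chrS", site_mids[k] - 6L, site_mids[k] + 6L,
             sprintf("site_%03d_%d", i, k))
    }

    ## TSS peaks realising the intended orientation class; a placement is
    ## accepted only if every in-window site agrees with the intended kind
    place_peak <- function(kind) {
      pw <- 20L
      for (try in 1:200) {
        ref <- site_mids[sample.int(length(site_mids), 1L)]
        d <- sample(80:420, 1L)
        left <- stats::runif(1) < 0.5
        pmid <- if (left) ref - d else ref + d
        strand <- if (kind == "inward") {
          if (left) "+" else "-"
        } else {
          if (left) "-" else "+"
        }
        ps <- pmid - pw %/% 2L; pe <- ps + pw
        ok <- TRUE
        for (sm in site_mids) {
          if (abs(pmid - sm) > window) next
          overlaps_site <- ps < sm + 6L && sm - 6L < pe
          inw <- overlaps_site ||
            (pmid < sm && strand == "+") || (pmid > sm && strand == "-")
          if ((kind == "inward") != inw) { ok <- FALSE; break }
        }
        if (ok) return(bed6("chrS", ps, pe,
                            sprintf("tss_%03d_%s", i, kind), 0L, strand))
      }
      NULL
    }
    cls <- classes[i]
    placed <- list()
    if (cls %in% c("inward", "both"))
      placed[[length(placed) + 1L]] <- place_peak("inward")
    if (cls %in% c("outward", "both"))
      placed[[length(placed) + 1L]] <- place_peak("outward")
    placed <- Filter(Negate(is.null), placed)
    realised <- cls
    if (cls != "none" && !length(placed)) realised <- "none"
    if (cls == "both" && length(placed) == 1L)
      realised <- sub("tss_\\d+_", "", placed[[1L]]$name)
    for (p in placed) peaks[[length(peaks) + 1L]] <- p
    if (cls == "none") {
      ## far peak outside every window, plus an unstranded decoy in-window
      far_mid <- max(site_mids) + window + 200L
      peaks[[length(peaks) + 1L]] <-
        bed6("chrS", far_mid - 10L, far_mid + 10L,
             sprintf("tss_%03d_far", i), 0L, sample(c("+", "-"), 1L))
      peaks[[length(peaks) + 1L]] <-
        bed6("chrS", site_mids[1L] + 100L, site_mids[1L] + 120L,
             sprintf("tss_%03d_unstranded", i), 0L, ".")
    }

    gt[[i]] <- data.frame(name = ename,
                          filtered_count = n_clean,
                          tss_score = n_clean / (enh_len / 1000),
                          orientation_class = realised,
                          stringsAsFactors = FALSE)
  }
  enh <- do.call(rbind, enh)
  exons <- do.call(rbind, exons)
  reads <- do.call(rbind, reads)
  tf_sites <- do.call(rbind, tf_sites)
  peaks <- do.call(rbind, peaks)
  gt <- do.call(rbind, gt)
  ## raw counts: clean reads plus any decoy/background read overlapping the
  ## enhancer (explicit arithmetic over the constructed table)
  gt$raw_count <- vapply(seq_len(nrow(enh)), function(j)
    sum(reads$start < enh$end[j] & enh$start[j] < reads$end), integer(1))
  gt <- gt[, c("name", "raw_count", "filtered_count", "tss_score",
               "orientation_class")]
  rownames(gt) <- NULL
  list(enhancers = enh, exons = exons, reads = reads, tf_sites = tf_sites,
       tss_peaks = peaks, ground_truth = gt)
}
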