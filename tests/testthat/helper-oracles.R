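## Independent reference implementations (oracles) used to validate the
## package's operations.  Deliberately written as plain iterative scans and
## quadratic loops, sharing no code with the package internals.

## ---- burst calling ---------------------------------------------------------

## Brute-force burst caller: lowess smooth, frame-by-frame threshold scan,
## iterative left-to-right valley splitting, minimum-duration filter.
oracle_call_bursts <- function(raw, threshold, window = 10L, min_dur = 5L) {
  n <- length(raw)
  f <- if (n < window) 1 else window / n
  sm <- suppressWarnings(stats::lowess(seq_len(n), raw, f = f, iter = 0,
                                       delta = 0)$y)
  above <- sm > threshold
  intervals <- list()
  t <- 1L
  while (t <= n) {
    if (above[t]) {
      s <- t
      while (t < n && above[t + 1L]) t <- t + 1L
      e <- t
      frag_start <- s
      k <- s + 2L
      while (k <= e - 2L) {
        if (k - 2L >= frag_start &&
            sm[k - 2L] > sm[k - 1L] && sm[k - 1L] > sm[k] &&
            sm[k] < sm[k + 1L] && sm[k + 1L] < sm[k + 2L]) {
          intervals[[length(intervals) + 1L]] <- c(frag_start, k - 1L)
          frag_start <- k
          k <- k + 2L
        } else {
          k <- k + 1L
        }
      }
      intervals[[length(intervals) + 1L]] <- c(frag_start, e)
    }
    t <- t + 1L
  }
  out <- data.frame(start = integer(), end = integer(),
                    duration = integer(), size = numeric())
  for (iv in intervals) {
    dur <- iv[2L] - iv[1L] + 1L
    if (dur >= min_dur)
      out <- rbind(out, data.frame(start = iv[1L], end = iv[2L],
                                   duration = dur,
                                   size = sum(raw[iv[1L]:iv[2L]])))
  }
  rownames(out) <- NULL
  out
}

## ---- exact rank-sum enumeration -------------------------------------------

## Exact two-sided rank-sum p-value by exhaustive enumeration of all
## choose(n_a + n_b, n_a) rank assignments (no ties assumed).
oracle_ranksum_p <- function(a, b) {
  n_a <- length(a)
  pooled <- rank(c(a, b))
  w_obs <- sum(pooled[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(length(pooled), n_a)
  w_all <- apply(combos, 2L, function(ix) sum(seq_along(pooled)[ix])) -
    n_a * (n_a + 1) / 2
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

## ---- genomic interval arithmetic (0-based half-open) -----------------------

oracle_overlaps <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

oracle_filter_reads <- function(reads, exons, margin = 50L) {
  keep <- rep(TRUE, nrow(reads))
  for (i in seq_len(nrow(reads))) {
    for (j in seq_len(nrow(exons))) {
      if (reads$chrom[i] == exons$chrom[j] &&
          oracle_overlaps(reads$start[i], reads$end[i],
                          max(0L, exons$start[j] - margin),
                          exons$end[j] + margin)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  reads[keep, , drop = FALSE]
}

oracle_score_enhancers <- function(reads, enhancers, exons, margin = 50L) {
  filt <- oracle_filter_reads(reads, exons, margin)
  raw <- integer(nrow(enhancers)); fc <- integer(nrow(enhancers))
  for (j in seq_len(nrow(enhancers))) {
    for (i in seq_len(nrow(reads))) {
      if (reads$chrom[i] == enhancers$chrom[j] &&
          oracle_overlaps(reads$start[i], reads$end[i],
                          enhancers$start[j], enhancers$end[j]))
        raw[j] <- raw[j] + 1L
    }
    for (i in seq_len(nrow(filt))) {
      if (filt$chrom[i] == enhancers$chrom[j] &&
          oracle_overlaps(filt$start[i], filt$end[i],
                          enhancers$start[j], enhancers$end[j]))
        fc[j] <- fc[j] + 1L
    }
  }
  data.frame(name = enhancers$name, raw_count = raw, filtered_count = fc,
             tss_score = fc / ((enhancers$end - enhancers$start) / 1000),
             stringsAsFactors = FALSE)
}

oracle_classify <- function(enhancers, tf_sites, tss_peaks, window = 500L) {
  peaks <- tss_peaks[tss_peaks$strand %in% c("+", "-"), , drop = FALSE]
  cls <- character(nrow(enhancers))
  for (e in seq_len(nrow(enhancers))) {
    has_in <- FALSE; has_out <- FALSE
    for (s in seq_len(nrow(tf_sites))) {
      if (tf_sites$chrom[s] != enhancers$chrom[e]) next
      if (!oracle_overlaps(tf_sites$start[s], tf_sites$end[s],
                           enhancers$start[e], enhancers$end[e])) next
      smid <- floor((tf_sites$start[s] + tf_sites$end[s]) / 2)
      for (p in seq_len(nrow(peaks))) {
        if (peaks$chrom[p] != tf_sites$chrom[s]) next
        pmid <- floor((peaks$start[p] + peaks$end[p]) / 2)
        if (abs(pmid - smid) > window) next
        inward <-
          oracle_overlaps(peaks$start[p], peaks$end[p],
                          tf_sites$start[s], tf_sites$end[s]) ||
          (pmid < smid && peaks$strand[p] == "+") ||
          (pmid > smid && peaks$strand[p] == "-") ||
          (pmid == smid)
        if (inward) has_in <- TRUE else has_out <- TRUE
      }
    }
    cls[e] <- if (has_in && has_out) "both" else if (has_in) "inward" else
      if (has_out) "outward" else "none"
  }
  data.frame(name = enhancers$name, orientation_class = cls,
             stringsAsFactors = FALSE)
}

## Random toy annotation (independent of the package's fixture generator),
## with systematic half-open boundary-offset reads around the first exon.
random_annotation <- function(seed) {
  set.seed(seed)
  mkbed <- function(n, lo, hi, wmin, wmax, prefix, strands = c("+", "-")) {
    s <- sample(lo:hi, n, replace = TRUE)
    w <- sample(wmin:wmax, n, replace = TRUE)
    data.frame(chrom = "chrT", start = s, end = s + w,
               name = sprintf("%s_%d", prefix, seq_len(n)), score = 0L,
               strand = sample(strands, n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  enhancers <- mkbed(sample(2:5, 1), 0L, 50000L, 400L, 2000L, "enh", ".")
  exons <- mkbed(sample(2:6, 1), 0L, 50000L, 80L, 500L, "exon", ".")
  reads <- mkbed(sample(10:40, 1), 0L, 52000L, 1L, 30L, "read")
  ## boundary-offset reads at +/- 2 bp around the expanded first exon
  ex <- exons[1L, ]
  extra <- list()
  for (d in -2:2) {
    re <- ex$start - 50L + d           # read end at the left expanded edge
    if (re >= 3L)
      extra[[length(extra) + 1L]] <-
        data.frame(chrom = "chrT", start = re - 3L, end = re,
                   name = sprintf("bnd_l_%d", d), score = 0L, strand = "+",
                   stringsAsFactors = FALSE)
    rs <- ex$end + 50L + d             # read start at the right expanded edge
    extra[[length(extra) + 1L]] <-
      data.frame(chrom = "chrT", start = rs, end = rs + 3L,
                 name = sprintf("bnd_r_%d", d), score = 0L, strand = "-",
                 stringsAsFactors = FALSE)
  }
  reads <- rbind(reads, do.call(rbind, extra))
  tf_sites <- mkbed(sample(2:6, 1), 0L, 50000L, 8L, 20L, "site", ".")
  tss_peaks <- mkbed(sample(4:12, 1), 0L, 50000L, 10L, 40L, "tss",
                     c("+", "-", "."))
  list(enhancers = enhancers, exons = exons, reads = reads,
       tf_sites = tf_sites, tss_peaks = tss_peaks)
}

## ---- image fixtures --------------------------------------------------------

## Label matrix with disks at the given centres (list of c(y, x)).
make_disk_mask <- function(ny, nx, centers, r) {
  m <- matrix(0L, ny, nx)
  for (i in seq_along(centers)) {
    cy <- centers[[i]][1L]; cx <- centers[[i]][2L]
    for (y in max(1, floor(cy - r)):min(ny, ceiling(cy + r)))
      for (x in max(1, floor(cx - r)):min(nx, ceiling(cx + r)))
        if ((y - cy)^2 + (x - cx)^2 <= r^2) m[y, x] <- i
  }
  m
}

## Intensity image with bright disks on a dark background.
make_disk_image <- function(ny, nx, centers, r, fg = 100, bg = 0) {
  m <- make_disk_mask(ny, nx, centers, r)
  out <- matrix(bg, ny, nx)
  out[m > 0L] <- fg
  out
}

## Minimal image_stack with a single channel from a list of 2D frames.
make_toy_stack <- function(frames, channel = "ms2") {
  tf <- length(frames)
  ny <- nrow(frames[[1L]]); nx <- ncol(frames[[1L]])
  a <- array(0, dim = c(tf, 1L, ny, nx))
  for (t in seq_len(tf)) a[t, 1L, , ] <- frames[[t]]
  structure(list(channels = stats::setNames(list(a), channel),
                 pixel_size_um = NA_real_, spec = NULL),
            class = "image_stack")
}
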