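bedrow <- function(start, end, strand = ".", name = "x", chrom = "chrT") {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = 0L, strand = strand, stringsAsFactors = FALSE)
}

test_that("exon filtering honours the 50-bp margin with half-open boundaries", {
  exon <- bedrow(1000L, 1100L, name = "exon")
  far <- bedrow(1300L, 1320L, name = "far")          # 200 bp away: retained
  inside <- bedrow(1050L, 1060L, name = "in")        # overlaps exon: removed
  reads <- rbind(far, inside)
  kept <- filter_exonic_reads(reads, exon)
  expect_identical(kept$name, "far")
  ## expanded exon is [950, 1150): scan read end/start offsets -2..+2
  for (d in -2:2) {
    r_left <- bedrow(940L, 950L + d, name = "l")
    r_right <- bedrow(1150L + d, 1170L, name = "r")
    kl <- nrow(filter_exonic_reads(r_left, exon)) == 1L
    kr <- nrow(filter_exonic_reads(r_right, exon)) == 1L
    expect_identical(kl, nrow(oracle_filter_reads(r_left, exon)) == 1L)
    expect_identical(kr, nrow(oracle_filter_reads(r_right, exon)) == 1L)
    expect_identical(kl, d <= 0)   # touch at the boundary is not overlap
    expect_identical(kr, d >= 0)
  }
  ## idempotence
  expect_identical(filter_exonic_reads(kept, exon), kept)
})

test_that("enhancer scores are filtered reads per kb of enhancer", {
  enh <- bedrow(10000L, 11000L, name = "e1")          # 1 kb
  exon <- bedrow(10000L, 10100L, name = "ex")         # overlaps enhancer head
  reads <- do.call(rbind, c(
    lapply(1:8, function(i) bedrow(10200L + 50L * i, 10210L + 50L * i,
                                   "+", sprintf("clean%d", i))),
    list(bedrow(10120L, 10130L, "+", "near_exon"),    # within 50 bp of exon
         bedrow(10090L, 10105L, "-", "on_exon"))))
  rec <- score_enhancers(reads, enh, exon)
  expect_identical(rec$raw_count, 10L)
  expect_identical(rec$filtered_count, 8L)
  expect_equal(rec$tss_score, 8)
  ## doubling the enhancer halves the score; zero reads give zero score
  enh2 <- bedrow(10000L, 12000L, name = "e1")
  expect_equal(score_enhancers(reads, enh2, exon)$tss_score, 4)
  empty <- bedrow(40000L, 41000L, name = "e0")
  expect_equal(score_enhancers(reads, empty, exon)$tss_score, 0)
  ## read-order invariance
  rec_shuffled <- score_enhancers(reads[rev(seq_len(nrow(reads))), ],
                                  enh, exon)
  expect_identical(rec$filtered_count, rec_shuffled$filtered_count)
})

test_that("malformed intervals are rejected with their line number", {
  bad <- rbind(bedrow(10L, 20L), bedrow(30L, 30L))
  expect_error(validate_intervals(bad, "read"), "line 2")
  badstrand <- bedrow(10L, 20L, strand = "x")
  expect_error(validate_intervals(badstrand), "line 1")
})

test_that("transcribed calls use >= with a strict exception at threshold 0", {
  rec <- data.frame(tss_score = c(0, 1, 5))
  ct <- call_transcribed(rec, 2)
  expect_identical(ct$records$transcribed, c(FALSE, FALSE, TRUE))
  ct0 <- call_transcribed(rec, 0)
  expect_identical(ct0$records$transcribed, c(FALSE, TRUE, TRUE))
  expect_true(all(diff(ct$cumulative$cum_fraction) >= 0))
  expect_equal(ct$cumulative$cum_fraction[nrow(rec)], 1)
})

test_that("TSS orientation follows strand and side relative to the site", {
  enh <- bedrow(9000L, 11000L, name = "e1")
  site <- bedrow(9994L, 10006L, name = "s1")          # midpoint 10000
  mk <- function(mid, strand, name) bedrow(mid - 10L, mid + 10L, strand, name)
  cases <- list(
    list(mk(9800L, "+", "t"), "inward"),    # rightward, toward the site
    list(mk(9800L, "-", "t"), "outward"),   # leftward, away from the site
    list(mk(10200L, "-", "t"), "inward"),
    list(mk(10200L, "+", "t"), "outward"),
    list(mk(10000L, "+", "t"), "inward"),   # overlaps the site itself
    list(mk(10600L, "+", "t"), "none"))     # beyond the 500-bp window
  for (cs in cases) {
    got <- classify_tss_orientation(enh, site, cs[[1L]])
    expect_identical(got$orientation_class, cs[[2L]])
    orc <- oracle_classify(enh, site, cs[[1L]])
    expect_identical(got$orientation_class, orc$orientation_class)
  }
  ## both kinds present -> "both"; unstranded peaks are skipped with warning
  both <- rbind(mk(9800L, "+", "a"), mk(10200L, "+", "b"))
  expect_identical(classify_tss_orientation(enh, site, both)$orientation_class,
                   "both")
  uns <- rbind(mk(9800L, "+", "a"), mk(10150L, ".", "u"))
  expect_warning(got <- classify_tss_orientation(enh, site, uns),
                 "skipped")
  expect_identical(got$orientation_class, "inward")
})

test_that("interval operations match the quadratic oracle on random annotations", {
  for (seed in 1:20) {
    ann <- random_annotation(seed)
    kept <- filter_exonic_reads(ann$reads, ann$exons)
    okept <- oracle_filter_reads(ann$reads, ann$exons)
    expect_identical(kept$name, okept$name)
    rec <- score_enhancers(ann$reads, ann$enhancers, ann$exons)
    orec <- oracle_score_enhancers(ann$reads, ann$enhancers, ann$exons)
    expect_identical(rec$raw_count, orec$raw_count)
    expect_identical(rec$filtered_count, orec$filtered_count)
    expect_equal(rec$tss_score, orec$tss_score)
    got <- suppressWarnings(
      classify_tss_orientation(ann$enhancers, ann$tf_sites, ann$tss_peaks))
    orc <- oracle_classify(ann$enhancers, ann$tf_sites, ann$tss_peaks)
    expect_identical(got$orientation_class, orc$orientation_class)
  }
})
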