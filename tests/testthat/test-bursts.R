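cfg10 <- burst_call_config(threshold = 2, lowess_window_frames = 10L)

test_that("lowess smoothing is exact on constants and lines, bounded on spikes", {
  expect_equal(smooth_trace(rep(3.5, 50), cfg10), rep(3.5, 50))
  ramp <- 2 + 0.7 * (1:60)
  expect_equal(smooth_trace(ramp, cfg10), ramp, tolerance = 1e-9)
  spike <- rep(0, 40); spike[20] <- 10
  sm <- smooth_trace(spike, cfg10)
  expect_lt(max(sm), 10)
  expect_gt(max(sm), 0)
  expect_warning(smooth_trace(rep(1, 5), cfg10), "shorter")
})

test_that("valley rule divides touching bursts exactly as specified", {
  expect_identical(split_touching_bursts(c(5, 4, 3, 2, 3, 4, 5)),
                   list(1:3, 4:7))
  expect_identical(split_touching_bursts(c(1, 2, 3, 4, 5)), list(1:5))
  ## plateau valley: strict inequalities fail, no split
  expect_identical(split_touching_bursts(c(5, 4, 3, 3, 4, 5)), list(1:6))
  ## two valleys, re-evaluated left to right on the remaining fragment
  s <- c(6, 5, 4, 5, 6, 5, 4, 5, 6)
  expect_identical(split_touching_bursts(s), list(1:2, 3:6, 7:9))
})

test_that("burst scan, duration filter and sizes follow the calling rules", {
  ## near-identity smoothing (2-frame window) to control runs exactly
  cfg2 <- burst_call_config(threshold = 2, lowess_window_frames = 2L,
                            min_duration_frames = 5L)
  zeros <- rep(0, 30)
  expect_identical(nrow(call_bursts(zeros, cfg2)), 0L)
  four <- rep(0, 30); four[10:13] <- 10          # 4 frames: false positive
  expect_identical(nrow(call_bursts(four, cfg2)), 0L)
  five <- rep(0, 30); five[10:14] <- c(10, 12, 11, 13, 10)
  b <- call_bursts(five, cfg2)
  expect_identical(nrow(b), 1L)
  expect_identical(c(b$start, b$end, b$duration), c(10L, 14L, 5L))
  expect_equal(b$size, sum(five[10:14]))
})

test_that("a block pulse is called as one burst matching the brute-force scan", {
  raw <- rep(0, 30); raw[5:12] <- 10
  b <- call_bursts(raw, cfg10)
  o <- oracle_call_bursts(raw, threshold = 2)
  expect_equal(b, o)
  expect_identical(nrow(b), 1L)
  expect_true(b$start <= 7 && b$end >= 10)       # covers the pulse core
  expect_equal(b$size, sum(raw[b$start:b$end]))
})

test_that("nucleus summaries count bursts and integrate the raw trace", {
  traces <- data.frame(
    lineage_id = rep(1:2, each = 40), channel = "ms2",
    frame = rep(1:40, 2),
    baseline_zeroed = c({x <- rep(0, 40); x[5:12] <- 10; x[25:32] <- 8; x},
                        rep(0, 40)))
  traces$raw <- traces$baseline_zeroed
  bursts <- call_all_bursts(traces, cfg10)
  summ <- summarize_nuclei(bursts, traces)
  expect_identical(summ$burst_frequency, c(2L, 0L))
  expect_equal(summ$total_output, c(80 + 64, 0))
  expect_identical(summ$ever_active, c(TRUE, FALSE))
  expect_identical(summ$onset[1], min(bursts$start))
  expect_true(is.na(summ$onset[2]))
  ## sum of burst sizes never exceeds the total output
  sizes <- tapply(bursts$size, bursts$lineage_id, sum)
  expect_true(all(sizes <= summ$total_output[match(names(sizes),
                                                   summ$lineage_id)]))
})

test_that("cumulative active fraction counts onsets as a monotone step curve", {
  summ <- data.frame(lineage_id = 1:4, onset = c(10L, 20L, 20L, NA))
  f <- cumulative_active_fraction(summ, 30L)
  expect_equal(f[9], 0); expect_equal(f[10], 0.25)
  expect_equal(f[19], 0.25); expect_equal(f[20], 0.75)
  expect_equal(f[30], 0.75)
  expect_true(all(diff(f) >= 0) && all(f >= 0 & f <= 1))
  expect_equal(cumulative_active_fraction(summ[0, ], 10L), rep(0, 10))
  all0 <- data.frame(lineage_id = 1:3, onset = c(1L, 1L, 1L))
  expect_equal(cumulative_active_fraction(all0, 5L), rep(1, 5))
})

test_that("instantaneous activity averages only currently bursting nuclei", {
  traces <- data.frame(lineage_id = rep(1:2, each = 20), channel = "pp7",
                       frame = rep(1:20, 2),
                       baseline_zeroed = c(rep(10, 20), rep(0, 20)))
  bursts <- data.frame(lineage_id = 1L, channel = "pp7",
                       start = 6L, end = 15L, duration = 10L, size = 100)
  ia <- instantaneous_activity(traces, bursts)
  expect_equal(ia$mean_activity[6:15], rep(10, 10))
  expect_true(all(is.na(ia$mean_activity[c(1:5, 16:20)])))
  ## two active nuclei at 4 and 8 average to 6
  traces$baseline_zeroed <- c(rep(4, 20), rep(8, 20))
  bursts2 <- rbind(bursts, data.frame(lineage_id = 2L, channel = "pp7",
                                      start = 6L, end = 15L, duration = 10L,
                                      size = 80))
  ia2 <- instantaneous_activity(traces, bursts2)
  expect_equal(ia2$mean_activity[10], 6)
  expect_identical(ia2$n_active[10], 2L)
})

test_that("activity stratified by partner-channel burst state recovers coupling", {
  ## MS2 signal constructed to be high exactly while PP7 bursts
  n <- 60L
  pp7_bursts <- data.frame(lineage_id = 1L, channel = "pp7",
                           start = 11L, end = 25L, duration = 15L, size = 0)
  ms2 <- rep(2, n); ms2[11:25] <- 8
  traces_ms2 <- data.frame(lineage_id = 1L, channel = "ms2", frame = 1:n,
                           baseline_zeroed = ms2)
  occ <- burst_occupancy(pp7_bursts, n)
  on_frames <- which(occ[1, ]); off_frames <- which(!occ[1, ])
  m_on <- mean(traces_ms2$baseline_zeroed[on_frames])
  m_off <- mean(traces_ms2$baseline_zeroed[off_frames])
  expect_equal(m_on, 8); expect_equal(m_off, 2)
  ## anticoupled construction flips the contrast
  ms2_anti <- rep(8, n); ms2_anti[11:25] <- 2
  expect_lt(mean(ms2_anti[on_frames]), mean(ms2_anti[off_frames]))
})

test_that("mean activity averages all analysed nuclei per frame", {
  traces <- data.frame(lineage_id = rep(1:2, each = 2), channel = "ms2",
                       frame = rep(1:2, 2),
                       baseline_zeroed = c(0, 2, 4, 6))
  ma <- mean_activity(traces)
  expect_equal(ma$mean_activity, c(2, 4))
  ## single nucleus: mean equals its trace
  one <- traces[traces$lineage_id == 1L, ]
  expect_equal(mean_activity(one)$mean_activity, one$baseline_zeroed)
})

test_that("rank-sum comparison matches exhaustive enumeration and caps Bonferroni", {
  a <- c(1, 2, 3); b <- c(10, 11, 12)
  res <- compare_groups(a, b)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_equal(oracle_ranksum_p(a, b), 0.1, tolerance = 1e-12)
  expect_equal(res$p_value, oracle_ranksum_p(a, b), tolerance = 1e-12)
  ## identical samples: p = 1 within the tie-handling convention
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p_value, 0.99)
  ## Bonferroni capping
  expect_equal(compare_groups(a, b, n_comparisons = 3)$adjusted_p,
               min(1, 0.1 * 3))
  expect_equal(compare_groups(c(0, 0, 5), c(9, 9, 9), 50)$adjusted_p, 1)
  expect_error(compare_groups(numeric(0), b), "non-empty")
})
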