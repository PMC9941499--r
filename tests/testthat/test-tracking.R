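test_that("a static nucleus yields one valid full-length lineage", {
  masks <- replicate(10, make_disk_mask(40, 40, list(c(20, 20)), 4),
                     simplify = FALSE)
  tracks <- apply_exclusions(link_frames(masks))
  expect_identical(length(unique(tracks$lineage_id)), 1L)
  expect_identical(nrow(tracks), 10L)
  expect_true(all(tracks$valid))
  expect_identical(unique(tracks$exclusion_reason), "none")
})

test_that("minimal-displacement matching preserves identities (no swap)", {
  ## nuclei approach each other; the correct assignment has total
  ## displacement 2*sqrt(2), the swapped one 2*sqrt(128)
  m1 <- make_disk_mask(40, 40, list(c(10, 10), c(30, 30)), 3)
  m2 <- make_disk_mask(40, 40, list(c(11, 11), c(29, 29)), 3)
  tracks <- link_frames(list(m1, m2))
  expect_identical(length(unique(tracks$lineage_id)), 2L)
  t1 <- tracks[tracks$frame == 1L, ]
  t2 <- tracks[tracks$frame == 2L, ]
  id_a <- t1$lineage_id[which.min(t1$y)]
  expect_equal(t2$y[t2$lineage_id == id_a], 11, tolerance = 0.2)
})

test_that("a jump larger than the nucleus length invalidates the lineage", {
  ## diameter-10 nucleus jumping 15 px
  m1 <- make_disk_mask(60, 60, list(c(30, 20)), 5)
  m2 <- make_disk_mask(60, 60, list(c(30, 35)), 5)
  tracks <- apply_exclusions(link_frames(list(m1, m2)))
  expect_true(all(!tracks$valid))
  expect_identical(unique(tracks$exclusion_reason), "jump_exceeds_length")
})

test_that("displacement exactly equal to the nucleus length is retained", {
  base <- data.frame(label = 1L, area = 25L, touches_edge = FALSE)
  mk <- function(disp, len) {
    tr <- rbind(cbind(data.frame(lineage_id = 1L, frame = 1L, y = 10,
                                 x = 10, major_axis = len), base),
                cbind(data.frame(lineage_id = 1L, frame = 2L, y = 10,
                                 x = 10 + disp, major_axis = len), base))
    class(tr) <- c("nucleus_tracks", "data.frame")
    tr
  }
  eq <- apply_exclusions(mk(disp = 8, len = 8))       # boundary: retained
  expect_true(all(eq$valid))
  over <- apply_exclusions(mk(disp = 8.0001, len = 8))  # strict >: excluded
  expect_true(all(!over$valid))
  expect_identical(unique(over$exclusion_reason), "jump_exceeds_length")
})

test_that("a region touching the image border excludes the whole lineage", {
  m1 <- make_disk_mask(40, 40, list(c(20, 5)), 3)   # interior
  m2 <- make_disk_mask(40, 40, list(c(20, 4)), 3)   # reaches column 1 here
  m3 <- make_disk_mask(40, 40, list(c(20, 5)), 3)
  tracks <- apply_exclusions(link_frames(list(m1, m2, m3)))
  expect_true(all(!tracks$valid))
  expect_identical(unique(tracks$exclusion_reason), "edge_contact")
})

test_that("an empty frame terminates active lineages", {
  m <- make_disk_mask(40, 40, list(c(20, 20)), 4)
  empty <- matrix(0L, 40, 40)
  tracks <- link_frames(list(m, empty, m))
  expect_identical(length(unique(tracks$lineage_id)), 2L)
  expect_identical(sort(tracks$frame), c(1L, 3L))
})

test_that("matching is injective and invariant to label permutation", {
  centers1 <- list(c(10, 10), c(10, 30), c(30, 10), c(30, 30))
  centers2 <- lapply(centers1, function(ct) ct + c(1, -1))
  m1 <- make_disk_mask(48, 48, centers1, 3)
  m2 <- make_disk_mask(48, 48, centers2, 3)
  ## permute labels of frame 2
  perm <- c(3L, 1L, 4L, 2L)
  m2p <- matrix(0L, 48, 48)
  for (k in 1:4) m2p[m2 == k] <- perm[k]
  tr_a <- link_frames(list(m1, m2))
  tr_b <- link_frames(list(m1, m2p))
  ## injective: one label per lineage per frame, one lineage per label
  for (tr in list(tr_a, tr_b)) {
    expect_false(any(duplicated(tr[, c("frame", "label")])))
    expect_false(any(duplicated(tr[, c("frame", "lineage_id")])))
  }
  ## same geometry: sorted per-lineage coordinate sequences agree
  geom <- function(tr) {
    s <- split(tr[, c("frame", "y", "x")], tr$lineage_id)
    s <- lapply(s, function(d) unname(as.matrix(d[order(d$frame), ])))
    s[order(vapply(s, function(m) m[1, 2] * 1000 + m[1, 3], numeric(1)))]
  }
  expect_equal(geom(tr_a), geom(tr_b))
})

test_that("tracking simulated movies reproduces ground-truth identities", {
  sim <- simulate_movie(movie_spec(n_nuclei = 12L,
                                   field_shape = c(30L, 3L, 150L, 150L),
                                   drift_sd_px = 0.4, seed = 31),
                        telegraph_params())
  masks <- lapply(1:30, function(t)
    segment_frame(max_project(sim$stack, "his2av", t)))
  tracks <- apply_exclusions(link_frames(masks))
  m <- liveburst:::match_tracks_to_truth(tracks, sim$ground_truth$nuclei)
  expect_identical(m$identity_swaps, 0L)
  expect_gte(length(unique(valid_tracks(tracks)$lineage_id)), 10L)
})
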