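test_that("trajectories order by onset with never-active nuclei last", {
  summ <- data.frame(lineage_id = 1:3, onset = c(30L, 10L, NA))
  expect_identical(order_trajectories(summ), c(2L, 1L, 3L))
  never <- data.frame(lineage_id = c(4L, 2L, 7L), onset = NA_integer_)
  expect_identical(order_trajectories(never), c(2L, 4L, 7L))
  ## channels are ordered independently
  summ2 <- data.frame(lineage_id = c(1:3, 1:3),
                      channel = rep(c("ms2", "pp7"), each = 3),
                      onset = c(30L, 10L, NA, 5L, NA, 1L))
  ms2 <- order_trajectories(summ2[summ2$channel == "ms2", ])
  pp7 <- order_trajectories(summ2[summ2$channel == "pp7", ])
  expect_identical(ms2, c(2L, 1L, 3L))
  expect_identical(pp7, c(3L, 1L, 2L))
})

test_that("false-colour maps scale with total output and ignore missing lineages", {
  mask <- matrix(0L, 20, 20)
  mask[2:5, 2:5] <- 1L; mask[10:13, 10:13] <- 2L
  tracks <- data.frame(lineage_id = 1:2, frame = 1L, label = 1:2,
                       y = c(3, 11), x = c(3, 11))
  summ <- data.frame(lineage_id = 1:2, total_output = c(50, 100))
  img <- false_color_map(mask, tracks, summ, frame = 1L)
  expect_equal(img[3, 3], 0.5)
  expect_equal(img[11, 11], 1)
  expect_equal(img[1, 1], 0)
  ## doubling all outputs leaves the normalised image identical
  summ2 <- summ; summ2$total_output <- summ2$total_output * 2
  expect_equal(false_color_map(mask, tracks, summ2, 1L), img)
  ## equal outputs give a uniform foreground
  summ3 <- summ; summ3$total_output <- c(70, 70)
  img3 <- false_color_map(mask, tracks, summ3, 1L)
  expect_identical(unique(img3[mask > 0L]), 1)
  ## a lineage missing from the mask is skipped with a warning
  summ4 <- rbind(summ, data.frame(lineage_id = 9L, total_output = 10))
  expect_warning(false_color_map(mask, tracks, summ4, 1L), "lineage 9")
})

test_that("image stacks and BED tables round-trip through files", {
  tmp <- withr::local_tempdir()
  sim <- simulate_movie(movie_spec(n_nuclei = 2L,
                                   field_shape = c(3L, 2L, 48L, 48L),
                                   seed = 12),
                        telegraph_params())
  path <- file.path(tmp, "stack.tiff")
  sc <- write_image_stack(sim$stack, path)
  rt <- read_image_stack(path, dims = c(3L, 2L),
                         channels = c("his2av", "ms2", "pp7"), scale = sc)
  expect_equal(rt$channels$ms2, pmax(sim$stack$channels$ms2, 0),
               tolerance = 1e-6)
  bed <- data.frame(chrom = "chrT", start = c(0L, 100L), end = c(50L, 230L),
                    name = c("a", "b"), score = c(1L, 2L),
                    strand = c("+", "-"), stringsAsFactors = FALSE)
  bp <- file.path(tmp, "toy.bed")
  write_bed6(bed, bp)
  rt2 <- read_bed6(bp)
  expect_identical(rt2$start, bed$start)
  expect_identical(rt2$end, bed$end)
  expect_identical(rt2$strand, bed$strand)
  expect_identical(rt2$name, bed$name)
})

test_that("the pipeline is deterministic, validates config, and runs genomics alone", {
  tmp <- withr::local_tempdir()
  cfg <- list(
    seed = 3L, output_dir = file.path(tmp, "run1"),
    movie = list(n_nuclei = 5L, field_shape = c(30L, 2L, 112L, 112L)),
    burst = list(threshold = 0.5 * 100 * 1.5 * gaussian_window_mass(1.5)))
  r1 <- run_pipeline(cfg)
  cfg$output_dir <- file.path(tmp, "run2")
  r2 <- run_pipeline(cfg)
  for (f in c("bursts.csv", "traces.csv", "summaries.csv", "tracks.csv"))
    expect_identical(unname(tools::md5sum(file.path(tmp, "run1", f))),
                     unname(tools::md5sum(file.path(tmp, "run2", f))))
  man <- jsonlite::read_json(file.path(tmp, "run1", "manifest.json"))
  expect_identical(man$status, "ok")
  expect_equal(man$config$seed, 3)
  expect_true(!is.null(man$config$burst$threshold))
  ## configuration errors are raised before any compute
  expect_error(run_pipeline(list(stages = "bursts")),
               class = "liveburst_pipeline_error")
  expect_error(run_pipeline(list(stages = c("simulate", "track"))),
               class = "liveburst_pipeline_error")
  expect_error(run_pipeline(list(channels = "gfp",
                                 burst = list(threshold = 1))),
               class = "liveburst_pipeline_error")
  ## genomics-only run needs no imaging input
  gcfg <- list(stages = "genomics", seed = 11L,
               output_dir = file.path(tmp, "gen"),
               genomics = list(n_enhancers = 6L, transcribed_threshold = 1))
  ## fixture "none" enhancers carry an unstranded decoy peak: skip warning
  expect_warning(rg <- run_pipeline(gcfg), "without strand")
  expect_true(file.exists(file.path(tmp, "gen", "enhancer_records.tsv")))
  expect_identical(nrow(rg$genomics), 6L)
})
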