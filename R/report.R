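#' Row ordering of trajectories by transcription onset
#'
#' Orders lineages by ascending onset of transcription (first retained
#' burst); never-active nuclei come last, ordered by lineage id.  MS2 and
#' PP7 orderings are computed separately by passing each channel's
#' summaries.
#'
#' @param summaries data.frame from [summarize_nuclei()] (one channel).
#' @return integer vector of lineage ids in display order.
#' @export
order_trajectories <- function(summaries) {
  onset <- summaries$onset
  ord <- order(is.na(onset), onset, summaries$lineage_id)
  summaries$lineage_id[ord]
}

#' False-colour map of per-nucleus total output
#'
#' Fills each nucleus region of a segmentation mask with a value
#' proportional to that nucleus's total transcriptional output (linear
#' scaling by the cohort maximum, so the image is invariant to rescaling
#' all outputs); background is 0.  Lineages without a region in the mask at
#' that frame are skipped with a warning.
#'
#' @param mask integer label matrix for the chosen frame.
#' @param tracks `nucleus_tracks` data.frame (maps lineage ids to labels).
#' @param summaries data.frame from [summarize_nuclei()] (one channel).
#' @param frame frame index of `mask`.
#' @return numeric matrix in `[0, 1]`.
#' @export
false_color_map <- function(mask, tracks, summaries, frame) {
  out <- matrix(0, nrow(mask), ncol(mask))
  sc <- max(summaries$total_output)
  if (sc <= 0) sc <- 1
  at_frame <- tracks[tracks$frame == frame, , drop = FALSE]
  for (k in seq_len(nrow(summaries))) {
    id <- summaries$lineage_id[k]
    row <- at_frame[at_frame$lineage_id == id, , drop = FALSE]
    if (!nrow(row)) {
      warning("lineage ", id, " has no region at frame ", frame, "; skipped")
      next
    }
    out[mask == row$label[1L]] <- summaries$total_output[k] / sc
  }
  out
}

pipeline_defaults <- function() {
  list(
    stages = c("simulate", "segment", "track", "trace", "bursts"),
    seed = 1L,
    output_dir = "liveburst_out",
    movie = list(n_nuclei = 10L, field_shape = c(60L, 3L, 128L, 128L),
                 nucleus_radius_px = 6, drift_sd_px = 0.3, psf_sd_px = 1.5,
                 background_level = 100, noise_sd = 5),
    kinetics = list(k_on = 0.05, k_off = 0.2, loading_rate = 1.5,
                    dwell_frames = 6L, intensity_per_transcript = 100),
    channels = c("ms2", "pp7"),
    burst = list(threshold = NULL, lowess_window_frames = 10L,
                 min_duration_frames = 5L),
    crop = NULL,
    genomics = list(n_enhancers = 20L, exon_margin_bp = 50L,
                    window_bp = 500L, transcribed_threshold = 1),
    write_tiff = FALSE)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

pipeline_error <- function(code, stage, message_text) {
  stop(structure(class = c("liveburst_pipeline_error", "error", "condition"),
                 list(message = sprintf("[%s] %s: %s", code, stage,
                                        message_text),
                      call = NULL, code = code, stage = stage)))
}

#' Run the analysis pipeline end to end
#'
#' Executes the selected stages in dependency order on a simulated movie
#' (`simulate`, `segment`, `track`, `trace`, `bursts`) and/or the genomics
#' analysis (`genomics`), writing CSV/TSV outputs and a JSON manifest
#' recording every parameter, seed and output checksum.  Identical
#' configuration yields byte-identical outputs.  Configuration errors are
#' raised before any computation; stage failures abort with a
#' machine-readable error after writing a partial manifest.
#'
#' The analysed window defaults to the movie's frame count; the imaging
#' field can be cropped with `crop = c(y0, y1, x0, x1)` before analysis to
#' restrict nuclei to an expression domain.
#'
#' @param config a nested list (see `pipeline_defaults` inside the
#'   function for the recognised fields) or the path to a YAML file.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_defaults(), config)
  stages <- cfg$stages
  known <- c("simulate", "segment", "track", "trace", "bursts", "genomics")
  if (length(bad <- setdiff(stages, known)))
    pipeline_error("config_error", "validate",
                   paste("unknown stage:", paste(bad, collapse = ", ")))
  imaging <- intersect(stages, known[1:5])
  if (length(imaging) && !identical(imaging, known[seq_along(imaging)]))
    pipeline_error("config_error", "validate",
                   "imaging stages must form a prefix of simulate>segment>track>trace>bursts")
  if (length(bad <- setdiff(cfg$channels, c("ms2", "pp7"))))
    pipeline_error("config_error", "validate",
                   paste("unknown channel:", paste(bad, collapse = ", ")))
  if ("bursts" %in% stages && is.null(cfg$burst$threshold))
    pipeline_error("config_error", "validate",
                   "burst$threshold is required (no default in the method)")
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(
                     utils::packageVersion("liveburst")),
                   config = cfg, outputs = list(), status = "running")
  write_manifest <- function() {
    jsonlite::write_json(manifest,
                         file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  emit <- function(name, df) {
    path <- file.path(cfg$output_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    manifest$outputs[[name]] <<- unname(tools::md5sum(path))
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn, error = function(e) {
      if (inherits(e, "liveburst_pipeline_error")) stop(e)
      manifest$status <<- "error"
      manifest$failed_stage <<- stage
      manifest$error <<- conditionMessage(e)
      write_manifest()
      pipeline_error("stage_failure", stage, conditionMessage(e))
    })
  }

  stack <- NULL; gt <- NULL; masks <- NULL; tracks <- NULL
  traces <- list(); bursts <- list(); summaries <- list()
  if ("simulate" %in% stages) run_stage("simulate", {
    spec <- do.call(movie_spec, c(cfg$movie, list(seed = cfg$seed)))
    par <- do.call(telegraph_params,
                   c(cfg$kinetics,
                     list(n_frames = cfg$movie$field_shape[1L],
                          seed = cfg$seed)))
    sim <- simulate_movie(spec, par)
    stack <- sim$stack; gt <- sim$ground_truth
    if (!is.null(cfg$crop)) {
      cr <- cfg$crop
      stack$channels <- lapply(stack$channels, function(a)
        a[, , cr[1L]:cr[2L], cr[3L]:cr[4L], drop = FALSE])
    }
    emit("ground_truth_traces.csv", gt$traces)
    if (isTRUE(cfg$write_tiff))
      write_image_stack(stack, file.path(cfg$output_dir, "movie.tiff"))
  })
  if ("segment" %in% stages) run_stage("segment", {
    if (is.null(stack$channels$his2av))
      pipeline_error("config_error", "segment", "missing his2av channel")
    sc <- segmentation_config()
    tf <- dim(stack$channels$his2av)[1L]
    masks <- lapply(seq_len(tf), function(t)
      segment_frame(max_project(stack, "his2av", t), sc))
  })
  if ("track" %in% stages) run_stage("track", {
    tracks <- apply_exclusions(link_frames(masks))
    emit("tracks.csv", as.data.frame(tracks))
  })
  if ("trace" %in% stages) run_stage("trace", {
    for (ch in cfg$channels) {
      if (is.null(stack$channels[[ch]]))
        pipeline_error("config_error", "trace",
                       paste("missing channel", ch))
      traces[[ch]] <- build_traces(stack, masks, tracks, ch)
    }
    emit("traces.csv", do.call(rbind, unname(lapply(traces, as.data.frame))))
  })
  if ("bursts" %in% stages) run_stage("bursts", {
    bc <- burst_call_config(cfg$burst$threshold,
                            cfg$burst$lowess_window_frames,
                            cfg$burst$min_duration_frames)
    for (ch in cfg$channels) {
      bursts[[ch]] <- call_all_bursts(traces[[ch]], bc)
      summaries[[ch]] <- summarize_nuclei(bursts[[ch]], traces[[ch]])
    }
    emit("bursts.csv", do.call(rbind, unname(bursts)))
    emit("summaries.csv", do.call(rbind, unname(summaries)))
  })
  genomics <- NULL
  if ("genomics" %in% stages) run_stage("genomics", {
    g <- cfg$genomics
    fx <- if (!is.null(g$enhancers_bed)) {
      list(enhancers = read_bed6(g$enhancers_bed),
           exons = read_bed6(g$exons_bed), reads = read_bed6(g$reads_bed),
           tf_sites = read_bed6(g$tf_sites_bed),
           tss_peaks = read_bed6(g$tss_peaks_bed))
    } else {
      simulate_genome_fixture(g$n_enhancers, seed = cfg$seed,
                              exon_margin_bp = g$exon_margin_bp,
                              window_bp = g$window_bp)
    }
    rec <- score_enhancers(fx$reads, fx$enhancers, fx$exons,
                           g$exon_margin_bp)
    rec <- call_transcribed(rec, g$transcribed_threshold)$records
    ori <- classify_tss_orientation(fx$enhancers, fx$tf_sites, fx$tss_peaks,
                                    g$window_bp)
    genomics <- merge(rec, ori, by = "name", sort = FALSE)
    path <- file.path(cfg$output_dir, "enhancer_records.tsv")
    utils::write.table(
      genomics[, c("chrom", "start", "end", "name", "raw_count",
                   "filtered_count", "tss_score", "transcribed",
                   "orientation_class")],
      path, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs[["enhancer_records.tsv"]] <- unname(tools::md5sum(path))
  })
  manifest$status <- "ok"
  write_manifest()
  invisible(list(manifest = manifest, tracks = tracks, traces = traces,
                 bursts = bursts, summaries = summaries,
                 genomics = genomics))
}
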