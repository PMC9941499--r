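#' Discrete Gaussian mass inside a square window
#'
#' Sum of a unit-peak isotropic 2D Gaussian over the `window_px x window_px`
#' pixel grid centred on the peak; the expected spot-extraction signal per
#' unit spot amplitude.
#'
#' @param sd Gaussian SD in pixels.
#' @param window_px odd window side (default 5).
#' @return a single number.
#' @export
gaussian_window_mass <- function(sd, window_px = 5L) {
  h <- (window_px - 1L) %/% 2L
  g <- exp(-(-h:h)^2 / (2 * sd^2))
  sum(outer(g, g))
}

## Match valid lineages to ground-truth nuclei by nearest centre per frame.
## Returns per-lineage majority ground-truth id and the number of identity
## switches along all lineages (0 = tracking never swapped identities).
match_tracks_to_truth <- function(tracks, gt_nuclei) {
  tr <- valid_tracks(tracks)
  swaps <- 0L
  assign_majority <- integer(0)
  ids <- unique(tr$lineage_id)
  gt_by_frame <- split(gt_nuclei, gt_nuclei$frame)
  for (id in ids) {
    g <- tr[tr$lineage_id == id, ]
    near <- vapply(seq_len(nrow(g)), function(k) {
      gf <- gt_by_frame[[as.character(g$frame[k])]]
      gf$nucleus_id[which.min((gf$y - g$y[k])^2 + (gf$x - g$x[k])^2)]
    }, integer(1))
    swaps <- swaps + sum(diff(near) != 0L)
    assign_majority[as.character(id)] <-
      as.integer(names(sort(table(near), decreasing = TRUE))[1L])
  }
  list(assignment = assign_majority, identity_swaps = swaps)
}

#' End-to-end burst parameter-recovery experiment
#'
#' For each promoter ON-rate, simulates full two-colour movies (several
#' seeds), runs segmentation, tracking, MS2 trace extraction and burst
#' calling, and compares per-cohort median burst frequency and size with
#' the simulation ground truth.  The burst threshold is fixed a priori at
#' half the extracted signal of a single transcript-frame
#' (`0.5 * intensity_per_transcript * loading_rate *`
#' [gaussian_window_mass()]), midway between the noise floor and the
#' one-transcript level.
#'
#' @param k_on_values promoter ON-rates to scan (per frame).
#' @param seeds integer seeds, one movie per seed per rate.
#' @param n_nuclei,n_frames cohort size per movie and analysed window.
#' @param params baseline [telegraph_params()] (its `k_on`, `n_frames` are
#'   overridden).
#' @param field `(Y, X)` pixel size of the simulated field.
#' @return data.frame per ON-rate: recovered `median_frequency` and
#'   `median_size`, ground-truth `gt_median_frequency`, `n_nuclei`
#'   analysed and total tracking `identity_swaps`.
#' @export
burst_recovery_experiment <- function(k_on_values = c(0.02, 0.05, 0.1),
                                      seeds = 1:3, n_nuclei = 20L,
                                      n_frames = 180L,
                                      params = telegraph_params(),
                                      field = c(160L, 160L)) {
  threshold <- 0.5 * params$intensity_per_transcript * params$loading_rate *
    gaussian_window_mass(1.5)
  bc <- burst_call_config(threshold)
  sc <- segmentation_config()
  out <- list()
  for (k_on in k_on_values) {
    freqs <- numeric(0); sizes <- numeric(0); gt_freqs <- numeric(0)
    swaps <- 0L
    for (seed in seeds) {
      spec <- movie_spec(n_nuclei = n_nuclei,
                         field_shape = c(n_frames, 3L, field[1L], field[2L]),
                         nucleus_radius_px = 6, drift_sd_px = 0.3,
                         psf_sd_px = 1.5, background_level = 100,
                         noise_sd = 5, seed = seed)
      par <- params
      par$k_on <- k_on
      par$n_frames <- n_frames
      class(par) <- "telegraph_params"
      sim <- simulate_movie(spec, par)
      masks <- lapply(seq_len(n_frames), function(t)
        segment_frame(max_project(sim$stack, "his2av", t), sc))
      tracks <- apply_exclusions(link_frames(masks))
      ## burst frequency is defined per analysed window: keep lineages
      ## tracked through the whole movie
      span <- tapply(tracks$frame, tracks$lineage_id, length)
      full <- as.integer(names(span)[span == n_frames])
      tracks$valid <- tracks$valid & tracks$lineage_id %in% full
      m <- match_tracks_to_truth(tracks, sim$ground_truth$nuclei)
      swaps <- swaps + m$identity_swaps
      traces <- build_traces(sim$stack, masks, tracks, "ms2")
      bursts <- call_all_bursts(traces, bc)
      summ <- summarize_nuclei(bursts, traces)
      freqs <- c(freqs, summ$burst_frequency)
      sizes <- c(sizes, bursts$size)
      gtb <- sim$ground_truth$bursts
      gt_freqs <- c(gt_freqs, vapply(m$assignment, function(nid)
        sum(gtb$nucleus_id == nid & gtb$channel == "ms2"), numeric(1)))
    }
    out[[length(out) + 1L]] <- data.frame(
      k_on = k_on,
      median_frequency = stats::median(freqs),
      median_size = stats::median(sizes),
      gt_median_frequency = stats::median(gt_freqs),
      n_nuclei = length(freqs),
      identity_swaps = swaps)
  }
  do.call(rbind, out)
}

## One single-nucleus hub mini-stack; returns site and random-site patches.
## The field outside the nucleus is set to the nuclear level: patches are
## measured in the nucleoplasm-interior regime (real nuclei are much larger
## than the 29 px patch), so control profiles sit on a uniform baseline.
hub_site_patch <- function(seed, amplitude_ratio, n_random = 0L,
                           side = 29L, nuclear_level = 200,
                           hub_sd_px = 3, noise_sd = 5) {
  spec <- movie_spec(n_nuclei = 1L, field_shape = c(1L, 3L, 64L, 64L),
                     nucleus_radius_px = 20, drift_sd_px = 0,
                     psf_sd_px = 1.5, background_level = nuclear_level,
                     noise_sd = noise_sd, seed = seed)
  hub <- simulate_hub_stack(spec, (amplitude_ratio - 1) * nuclear_level,
                            hub_sd_px = hub_sd_px,
                            nuclear_level = nuclear_level)
  region <- label_region_3d(hub$ground_truth$labels, dim(hub$tf)[1L], 1L)
  site <- extract_patch(hub$tf, hub$spot, region, side)
  rand <- list()
  if (n_random > 0L) {
    z0 <- hub$ground_truth$spots$z[1L]
    rand <- with_seed(substream_seed(seed, 9L), lapply(seq_len(n_random),
      function(i) sample_random_site(hub$tf, region, z0, side)))
  }
  list(site = site, random = rand, hub = hub)
}

#' Hub enrichment recovery and null-calibration experiment
#'
#' Simulates single-nucleus 3D stacks with injected Gaussian hubs at the
#' requested centre-to-nucleoplasm amplitude ratios (`n_sites` independent
#' stacks per ratio), extracts transcription-site patches using the
#' ground-truth regions, and computes the radial enrichment profile per
#' ratio, the closed-form expected central-bin enrichment, and a
#' random-site control pooled over the ratio-1 stacks.
#'
#' @param amplitude_ratios centre intensity ratios (1 = no hub).
#' @param n_sites sites (stacks) per ratio.
#' @param seed base seed.
#' @param n_random_per_site random control sites drawn per ratio-1 stack.
#' @param side patch side in pixels.
#' @return list with `summary` (data.frame: ratio, central enrichment,
#'   closed form), `profiles` (per-ratio profile data.frames),
#'   `patches` (per-ratio patch lists) and `random_profile`.
#' @export
hub_recovery_experiment <- function(amplitude_ratios = c(1, 1.25, 1.5, 2),
                                    n_sites = 50L, seed = 1L,
                                    n_random_per_site = 4L, side = 29L) {
  hub_sd <- 3; level <- 200
  r_end <- (side - 1L) %/% 2L
  profiles <- list(); patches <- list(); rand_patches <- list()
  summary <- list()
  for (j in seq_along(amplitude_ratios)) {
    rho <- amplitude_ratios[j]
    ps <- lapply(seq_len(n_sites), function(i) {
      hp <- hub_site_patch(substream_seed(seed, 10L + j, i), rho,
                           n_random = if (rho == 1) n_random_per_site else 0L,
                           side = side, nuclear_level = level,
                           hub_sd_px = hub_sd)
      if (rho == 1) rand_patches[[length(rand_patches) + 1L]] <<- hp$random
      hp$site
    })
    patches[[as.character(rho)]] <- ps
    re <- radial_enrichment(ps)
    profiles[[as.character(rho)]] <- re$profile
    alpha <- rho - 1
    closed <- (1 + alpha) /
      (1 + alpha * exp(-r_end^2 / (2 * hub_sd^2)))
    summary[[j]] <- data.frame(
      amplitude_ratio = rho,
      central_enrichment =
        re$profile$mean_relative_enrichment[re$profile$bin == 0L],
      closed_form = closed)
  }
  random_profile <- if (length(rand_patches))
    radial_enrichment(unlist(rand_patches, recursive = FALSE))$profile
  else NULL
  list(summary = do.call(rbind, summary), profiles = profiles,
       patches = patches, random_profile = random_profile)
}

#' Monte-Carlo power of the radial-curve area comparison
#'
#' Repeatedly simulates two cohorts of hub stacks (amplitude ratios
#' `ratio_a` vs `ratio_b`, `n_sites` sites each), compares their per-site
#' radial-curve areas with the two-sided rank-sum test, and reports the
#' fraction of repetitions rejecting at `alpha`.
#'
#' @param n_reps repetitions.
#' @param n_sites sites per cohort per repetition.
#' @param seed base seed.
#' @param ratio_a,ratio_b amplitude ratios of the two conditions.
#' @param alpha rejection level (default 0.01).
#' @return list with `rejection_rate` and the vector of `p_values`.
#' @export
hub_power_experiment <- function(n_reps = 100L, n_sites = 50L, seed = 1L,
                                 ratio_a = 1, ratio_b = 2, alpha = 0.01) {
  p_values <- vapply(seq_len(n_reps), function(rep) {
    pa <- lapply(seq_len(n_sites), function(i)
      hub_site_patch(substream_seed(seed, 20L + rep, i), ratio_a)$site)
    pb <- lapply(seq_len(n_sites), function(i)
      hub_site_patch(substream_seed(seed, 120L + rep, i), ratio_b)$site)
    compare_profile_areas(pa, pb)$p_value
  }, numeric(1))
  list(rejection_rate = mean(p_values < alpha), p_values = p_values)
}
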