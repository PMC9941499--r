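#' Specification of a synthetic imaging field
#'
#' Describes the synthetic microscope field used by [simulate_movie()] and
#' [simulate_hub_stack()]: a `T x Z x Y x X` voxel grid carrying near-circular
#' nuclei (rendered as disks, constant across z) whose centroids jitter
#' frame-to-frame around their placed positions, with diffraction-limited
#' transcription spots rendered as isotropic 3D Gaussians at the nucleus
#' centers.
#'
#' Nuclei are placed by rejection sampling with a hard minimum centre spacing
#' of 2.5 nucleus radii, so segmentation difficulty is controlled and regions
#' never overlap at t = 0.
#'
#' @param n_nuclei number of nuclei (>= 1).
#' @param field_shape integer vector `(T, Z, Y, X)` of voxel counts.
#' @param nucleus_radius_px nucleus radius in pixels.
#' @param drift_sd_px per-frame SD of the centroid random-walk step (pixels).
#' @param psf_sd_px Gaussian SD of the rendered spot (pixels, isotropic).
#' @param background_level constant background intensity (arbitrary units).
#' @param noise_sd SD of additive Gaussian voxel noise.
#' @param pixel_size_um physical pixel size, metadata only.
#' @param seed integer seed.
#' @return an object of class `movie_spec`.
#' @export
movie_spec <- function(n_nuclei = 10L, field_shape = c(60L, 3L, 128L, 128L),
                       nucleus_radius_px = 6, drift_sd_px = 0.3,
                       psf_sd_px = 1.5, background_level = 100, noise_sd = 5,
                       pixel_size_um = 0.2, seed = 1L) {
  assert_scalar_num(n_nuclei, "n_nuclei", 1, integer = TRUE)
  if (length(field_shape) != 4L || any(field_shape < 1))
    stop("'field_shape' must be positive (T, Z, Y, X)", call. = FALSE)
  assert_scalar_num(nucleus_radius_px, "nucleus_radius_px", 1)
  assert_scalar_num(drift_sd_px, "drift_sd_px", 0)
  assert_scalar_num(psf_sd_px, "psf_sd_px", 0.1)
  assert_scalar_num(background_level, "background_level", 0)
  assert_scalar_num(noise_sd, "noise_sd", 0)
  assert_scalar_num(seed, "seed", integer = TRUE)
  structure(list(n_nuclei = as.integer(n_nuclei),
                 field_shape = as.integer(field_shape),
                 nucleus_radius_px = nucleus_radius_px,
                 drift_sd_px = drift_sd_px, psf_sd_px = psf_sd_px,
                 background_level = background_level, noise_sd = noise_sd,
                 pixel_size_um = pixel_size_um, seed = as.integer(seed)),
            class = "movie_spec")
}

## Rejection-sample nucleus centres with min spacing 2.5 r and an edge margin.
## Returns an n x 2 matrix (y, x); errors out after bounded retries.
place_nuclei <- function(spec, margin = NULL, max_tries = 20000L) {
  ny <- spec$field_shape[3L]; nx <- spec$field_shape[4L]
  r <- spec$nucleus_radius_px
  if (is.null(margin)) margin <- r + 1
  min_d2 <- (2.5 * r)^2
  if (ny - 2 * margin <= 0 || nx - 2 * margin <= 0)
    stop("field too small for nucleus radius", call. = FALSE)
  centers <- matrix(NA_real_, spec$n_nuclei, 2L)
  placed <- 0L
  for (i in seq_len(max_tries)) {
    cand <- c(stats::runif(1, margin, ny - margin),
              stats::runif(1, margin, nx - margin))
    if (placed == 0L ||
        all((centers[seq_len(placed), 1L] - cand[1L])^2 +
            (centers[seq_len(placed), 2L] - cand[2L])^2 >= min_d2)) {
      placed <- placed + 1L
      centers[placed, ] <- cand
      if (placed == spec$n_nuclei) return(centers)
    }
  }
  stop("could not place ", spec$n_nuclei,
       " non-overlapping nuclei after ", max_tries, " tries", call. = FALSE)
}

## Add an isotropic 3D Gaussian of amplitude `amp`, SD `sd`, centred at
## (z0, y0, x0) (continuous coords) to array `a` [Z, Y, X], in place-ish.
add_gaussian_3d <- function(a, z0, y0, x0, amp, sd, half = NULL) {
  if (amp <= 0) return(a)
  d <- dim(a)
  if (is.null(half)) half <- ceiling(3 * sd)
  ys <- max(1L, floor(y0 - half)):min(d[2L], ceiling(y0 + half))
  xs <- max(1L, floor(x0 - half)):min(d[3L], ceiling(x0 + half))
  zs <- seq_len(d[1L])
  if (!length(ys) || !length(xs)) return(a)
  gy <- exp(-(ys - y0)^2 / (2 * sd^2))
  gx <- exp(-(xs - x0)^2 / (2 * sd^2))
  gz <- exp(-(zs - z0)^2 / (2 * sd^2))
  blob <- outer(gy, gx)  # [y, x]
  for (k in seq_along(zs))
    a[zs[k], ys, xs] <- a[zs[k], ys, xs] + amp * gz[k] * blob
  a
}

## Boolean disk mask contribution: pixel indices within radius r of (cy, cx).
disk_pixels <- function(ny, nx, cy, cx, r) {
  ys <- max(1L, floor(cy - r)):min(ny, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(nx, ceiling(cx + r))
  g <- expand.grid(y = ys, x = xs)
  keep <- (g$y - cy)^2 + (g$x - cx)^2 <= r^2
  g[keep, , drop = FALSE]
}

#' Simulate a two-colour live-imaging movie with ground truth
#'
#' Renders a nuclear-marker (`his2av`) channel of jittering blurred disks and
#' `ms2`/`pp7` spot channels in which each nucleus carries an isotropic 3D
#' Gaussian spot at its centre whose amplitude follows an independent
#' telegraph-model clean trace (see [simulate_trace()]).  All channels sit on
#' `background_level` plus Gaussian voxel noise.
#'
#' Random streams are split per nucleus, so simulating more nuclei leaves the
#' traces and drift of existing nuclei unchanged.
#'
#' @param spec a [movie_spec()].
#' @param params a [telegraph_params()]; its `n_frames` and `seed` are
#'   overridden by the movie's frame count and per-nucleus streams, and its
#'   `noise_sd` is ignored (voxel noise comes from `spec$noise_sd`).
#' @return list with `stack` (class `image_stack`: list of per-channel
#'   `[T, Z, Y, X]` arrays plus metadata) and `ground_truth` (nucleus
#'   positions per frame, clean MS2/PP7 traces and states, true burst
#'   intervals, initial centres, radius).
#' @export
simulate_movie <- function(spec, params = telegraph_params()) {
  stopifnot(inherits(spec, "movie_spec"), inherits(params, "telegraph_params"))
  tf <- spec$field_shape[1L]; nz <- spec$field_shape[2L]
  ny <- spec$field_shape[3L]; nx <- spec$field_shape[4L]
  n <- spec$n_nuclei
  centers <- with_seed(substream_seed(spec$seed, 0L), place_nuclei(spec))

  p <- params
  p$n_frames <- tf
  ## per-nucleus drift and channel traces from independent substreams
  drift <- vector("list", n)
  sims <- vector("list", n)
  for (i in seq_len(n)) {
    drift[[i]] <- with_seed(substream_seed(spec$seed, 1L, i), {
      ## stationary per-frame jitter around the placed centre: nuclei wobble
      ## but never wander into each other (nc14 nuclei do not interpenetrate)
      dy <- stats::rnorm(tf, sd = spec$drift_sd_px)
      dx <- stats::rnorm(tf, sd = spec$drift_sd_px)
      cbind(centers[i, 1L] + dy - dy[1L], centers[i, 2L] + dx - dx[1L])
    })
    sims[[i]] <- list(
      ms2 = with_seed(substream_seed(spec$seed, 2L, i), simulate_trace_impl(p)),
      pp7 = with_seed(substream_seed(spec$seed, 3L, i), simulate_trace_impl(p)))
  }

  z0 <- (nz + 1) / 2
  his_amp <- 4 * max(spec$background_level, 1)
  mk_noise <- function(stream) with_seed(substream_seed(spec$seed, stream),
    array(stats::rnorm(tf * nz * ny * nx, sd = spec$noise_sd),
          dim = c(tf, nz, ny, nx)))
  his <- mk_noise(4L) + spec$background_level
  ms2 <- mk_noise(5L) + spec$background_level
  pp7 <- mk_noise(6L) + spec$background_level

  for (t in seq_len(tf)) {
    ## nuclear marker: blurred disks, identical across z (prism)
    frame2d <- matrix(0, ny, nx)
    for (i in seq_len(n)) {
      px <- disk_pixels(ny, nx, drift[[i]][t, 1L], drift[[i]][t, 2L],
                        spec$nucleus_radius_px)
      frame2d[cbind(px$y, px$x)] <- his_amp
    }
    frame2d <- as_mat(EBImage::gblur(EBImage::Image(frame2d), sigma = 1))
    spot_ms2 <- array(0, dim = c(nz, ny, nx))
    spot_pp7 <- array(0, dim = c(nz, ny, nx))
    for (i in seq_len(n)) {
      cy <- drift[[i]][t, 1L]; cx <- drift[[i]][t, 2L]
      spot_ms2 <- add_gaussian_3d(spot_ms2, z0, cy, cx,
                                  sims[[i]]$ms2$trace$clean[t], spec$psf_sd_px)
      spot_pp7 <- add_gaussian_3d(spot_pp7, z0, cy, cx,
                                  sims[[i]]$pp7$trace$clean[t], spec$psf_sd_px)
    }
    for (z in seq_len(nz)) {
      his[t, z, , ] <- his[t, z, , ] + frame2d
      ms2[t, z, , ] <- ms2[t, z, , ] + spot_ms2[z, , ]
      pp7[t, z, , ] <- pp7[t, z, , ] + spot_pp7[z, , ]
    }
  }

  nuclei <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(nucleus_id = i, frame = seq_len(tf),
               y = drift[[i]][, 1L], x = drift[[i]][, 2L])))
  traces <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(nucleus_id = i, frame = seq_len(tf),
               clean_ms2 = sims[[i]]$ms2$trace$clean,
               clean_pp7 = sims[[i]]$pp7$trace$clean,
               state_ms2 = sims[[i]]$ms2$ground_truth$promoter_state,
               state_pp7 = sims[[i]]$pp7$ground_truth$promoter_state)))
  bursts <- do.call(rbind, lapply(seq_len(n), function(i) {
    rbind_channels <- function(ch) {
      b <- sims[[i]][[ch]]$ground_truth$true_bursts
      if (!nrow(b)) return(NULL)
      data.frame(nucleus_id = i, channel = ch, start = b$start, end = b$end)
    }
    rbind(rbind_channels("ms2"), rbind_channels("pp7"))
  }))
  if (is.null(bursts))
    bursts <- data.frame(nucleus_id = integer(), channel = character(),
                         start = integer(), end = integer())

  stack <- structure(list(channels = list(his2av = his, ms2 = ms2, pp7 = pp7),
                          pixel_size_um = spec$pixel_size_um,
                          spec = spec),
                     class = "image_stack")
  list(stack = stack,
       ground_truth = list(nuclei = nuclei, traces = traces, bursts = bursts,
                           centers = centers,
                           radius = spec$nucleus_radius_px, params = p))
}

#' Maximum z-projection of one timeframe of a channel
#'
#' @param stack an `image_stack` from [simulate_movie()].
#' @param channel channel name.
#' @param frame frame index (1-based).
#' @return a `[Y, X]` intensity matrix.
#' @export
max_project <- function(stack, channel, frame) {
  a <- stack$channels[[channel]]
  if (is.null(a)) stop("channel '", channel, "' not present", call. = FALSE)
  nz <- dim(a)[2L]
  out <- a[frame, 1L, , ]
  if (nz > 1L) for (z in 2:nz) out <- pmax(out, a[frame, z, , ])
  out
}

#' Simulate a single-timepoint 3D stack with a transcription-factor hub
#'
#' Renders a two-channel `Z x Y x X` stack: a TF channel with a uniform
#' nuclear level inside each nucleus plus an isotropic 3D Gaussian "hub" of
#' amplitude `hub_amplitude` centred on the transcription spot, and a spot
#' channel marking the spot location.  Spots sit at the nucleus centres on
#' the middle z-slice.  Both channels carry `background_level` outside nuclei
#' and Gaussian voxel noise.
#'
#' @param spec a [movie_spec()]; only `(Z, Y, X)` of `field_shape` are used.
#' @param hub_amplitude peak hub intensity above the nuclear level (>= 0).
#' @param hub_sd_px Gaussian SD of the hub (pixels, isotropic).
#' @param nuclear_level uniform TF intensity inside nuclei.
#' @return list with `tf` and `spot` arrays `[Z, Y, X]` and `ground_truth`
#'   (2D nucleus label matrix, per-nucleus spot voxels, parameters).
#' @export
simulate_hub_stack <- function(spec, hub_amplitude, hub_sd_px = 3,
                               nuclear_level = 200) {
  stopifnot(inherits(spec, "movie_spec"))
  assert_scalar_num(hub_amplitude, "hub_amplitude", 0)
  assert_scalar_num(hub_sd_px, "hub_sd_px", 0.1)
  nz <- spec$field_shape[2L]; ny <- spec$field_shape[3L]
  nx <- spec$field_shape[4L]
  centers <- with_seed(substream_seed(spec$seed, 0L), place_nuclei(spec))
  centers <- round(centers)
  z0 <- as.integer(ceiling(nz / 2))

  labels <- matrix(0L, ny, nx)
  tf <- array(spec$background_level, dim = c(nz, ny, nx))
  for (i in seq_len(spec$n_nuclei)) {
    px <- disk_pixels(ny, nx, centers[i, 1L], centers[i, 2L],
                      spec$nucleus_radius_px)
    labels[cbind(px$y, px$x)] <- i
    for (z in seq_len(nz))
      tf[z, , ][cbind(px$y, px$x)] <- nuclear_level
  }
  spot <- array(spec$background_level, dim = c(nz, ny, nx))
  for (i in seq_len(spec$n_nuclei)) {
    tf <- add_gaussian_3d(tf, z0, centers[i, 1L], centers[i, 2L],
                          hub_amplitude, hub_sd_px)
    spot <- add_gaussian_3d(spot, z0, centers[i, 1L], centers[i, 2L],
                            1000, spec$psf_sd_px)
  }
  nvox <- nz * ny * nx
  tf <- tf + with_seed(substream_seed(spec$seed, 7L),
    array(stats::rnorm(nvox, sd = spec$noise_sd), dim = c(nz, ny, nx)))
  spot <- spot + with_seed(substream_seed(spec$seed, 8L),
    array(stats::rnorm(nvox, sd = spec$noise_sd), dim = c(nz, ny, nx)))

  spots <- data.frame(nucleus_id = seq_len(spec$n_nuclei),
                      z = z0, y = centers[, 1L], x = centers[, 2L])
  list(tf = tf, spot = spot,
       ground_truth = list(labels = labels, spots = spots,
                           hub_amplitude = hub_amplitude,
                           hub_sd_px = hub_sd_px,
                           nuclear_level = nuclear_level,
                           background_level = spec$background_level))
}
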