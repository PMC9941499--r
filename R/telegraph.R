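#' Telegraph-model parameters for a simulated promoter
#'
#' The synthetic-data generator models each promoter as a two-state
#' (ON/OFF) telegraph process observed at discrete timeframes.  While ON,
#' the promoter loads `loading_rate` transcripts per frame; each nascent
#' transcript contributes `intensity_per_transcript` units of signal for
#' `dwell_frames` consecutive frames (a boxcar dwell).  The observed trace
#' is the noise-free ("clean") trace plus additive Gaussian noise, clipped
#' at zero.
#'
#' `k_on` and `k_off` are per-frame switching probabilities:
#' OFF -> ON with probability `k_on`, ON -> OFF with probability `k_off`.
#' The long-run fraction of ON frames is therefore `k_on / (k_on + k_off)`.
#'
#' @param k_on OFF to ON switching probability per frame, in `[0, 1]`.
#' @param k_off ON to OFF switching probability per frame, in `[0, 1]`.
#' @param loading_rate transcripts initiated per frame while ON (>= 0).
#' @param dwell_frames frames a nascent transcript contributes signal (>= 1).
#' @param intensity_per_transcript signal per transcript, arbitrary units.
#' @param noise_sd SD of additive Gaussian noise on the observed trace.
#' @param n_frames number of timeframes to simulate (>= 1).
#' @param seed integer seed; simulation is bit-reproducible given the seed.
#' @return an object of class `telegraph_params`.
#' @seealso [simulate_trace()]
#' @export
telegraph_params <- function(k_on = 0.05, k_off = 0.2, loading_rate = 1.5,
                             dwell_frames = 6L, intensity_per_transcript = 100,
                             noise_sd = 25, n_frames = 180L, seed = 1L) {
  assert_scalar_num(k_on, "k_on", 0, 1)
  assert_scalar_num(k_off, "k_off", 0, 1)
  assert_scalar_num(loading_rate, "loading_rate", 0)
  assert_scalar_num(dwell_frames, "dwell_frames", 1, integer = TRUE)
  assert_scalar_num(intensity_per_transcript, "intensity_per_transcript", 0)
  assert_scalar_num(noise_sd, "noise_sd", 0)
  assert_scalar_num(n_frames, "n_frames", 1, integer = TRUE)
  assert_scalar_num(seed, "seed", integer = TRUE)
  structure(list(k_on = k_on, k_off = k_off, loading_rate = loading_rate,
                 dwell_frames = as.integer(dwell_frames),
                 intensity_per_transcript = intensity_per_transcript,
                 noise_sd = noise_sd, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "telegraph_params")
}

## Simulate the ON/OFF state sequence of the two-state chain.  The initial
## state is drawn from the stationary distribution (OFF when both rates are
## zero), so k_off = 0 with k_on > 0 starts, and stays, ON.
simulate_states <- function(k_on, k_off, n_frames) {
  s <- logical(n_frames)
  p_on <- if (k_on + k_off > 0) k_on / (k_on + k_off) else 0
  s[1L] <- stats::runif(1L) < p_on
  if (n_frames > 1L) {
    u <- stats::runif(n_frames - 1L)
    for (t in 2:n_frames) {
      s[t] <- if (s[t - 1L]) u[t - 1L] >= k_off else u[t - 1L] < k_on
    }
  }
  s
}

#' Simulate a single promoter trace with ground truth
#'
#' Runs the two-state telegraph chain, convolves per-frame initiation
#' (`loading_rate` while ON) with a `dwell_frames` boxcar scaled by
#' `intensity_per_transcript` to obtain the clean trace, and adds Gaussian
#' noise clipped at zero to obtain the observed trace.  Ground-truth bursts
#' are the maximal runs of frames with a positive clean trace.
#'
#' Frames are indexed 1..n_frames; burst `start`/`end` are inclusive frame
#' indices.
#'
#' @param params a [telegraph_params()] object.
#' @return a list with elements
#'   * `trace`: data.frame `(frame, raw, clean)` — `raw` is the observed
#'     (noisy, zero-clipped) intensity;
#'   * `ground_truth`: list with `promoter_state` (logical per frame),
#'     `true_bursts` (data.frame `start`, `end`), `clean_trace`, and the
#'     input `params`.
#' @examples
#' tr <- simulate_trace(telegraph_params(k_on = 0.05, k_off = 0.2, seed = 7))
#' nrow(tr$ground_truth$true_bursts)
#' @export
simulate_trace <- function(params) {
  stopifnot(inherits(params, "telegraph_params"))
  with_seed(params$seed, simulate_trace_impl(params))
}

## Core simulation using the current RNG stream (no seeding); used by
## simulate_movie with per-nucleus substreams.
simulate_trace_impl <- function(params) {
  n <- params$n_frames
  state <- simulate_states(params$k_on, params$k_off, n)
  init <- params$loading_rate * as.numeric(state)
  d <- params$dwell_frames
  ## boxcar convolution: clean[t] = sum of initiations over frames t-d+1 .. t
  padded <- c(rep(0, d - 1L), init)
  clean <- as.numeric(stats::filter(padded, rep(1, d), sides = 1L))[
    d:(n + d - 1L)] * params$intensity_per_transcript
  clean[abs(clean) < 1e-12] <- 0  # guard tiny negative fp residue
  raw <- pmax(0, clean + stats::rnorm(n, sd = params$noise_sd))
  list(
    trace = data.frame(frame = seq_len(n), raw = raw, clean = clean),
    ground_truth = list(promoter_state = state,
                        true_bursts = runs_true(clean > 0),
                        clean_trace = clean,
                        params = params)
  )
}
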