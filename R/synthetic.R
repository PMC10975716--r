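## Synthetic squat-cohort generator with known ground truth. Marker
## amplitudes are anchored to the reference cohort's displacement table
## (barbell ~62 +/- 9 cm, hip ~32 +/- 6 cm, knee ~9 +/- 2 cm,
## ankle ~0.5 +/- 0.3 cm at no load).

#' Parameters of the synthetic squat generator
#'
#' Defaults emulate the reference study conditions: ten lifters, loads of 0,
#' 50 and 75 percent of body weight, three repetitions per load, 30 frames/s,
#' a 3-second repetition (90 frames), and per-marker vertical amplitudes
#' drawn once per subject from normal distributions matched to the cohort
#' displacement table. Each marker's y follows a half-cosine descent then a
#' half-cosine ascent (single interior minimum); x performs a small coupled
#' horizontal excursion proportional to the vertical amplitude. Load adds a
#' configurable vertical-amplitude shift and horizontal drift, and i.i.d.
#' Gaussian positional noise of \code{noise_sd} cm is added per frame.
#'
#' @param n_subjects number of subjects.
#' @param loads barbell loads in percent body weight.
#' @param reps_per_load repetitions per load (\eqn{\ge 1}).
#' @param fps frames per second.
#' @param duration_frames frames per repetition (descent + ascent).
#' @param amplitude_mean,amplitude_sd named numeric vectors (barbell, hip,
#'   knee, ankle): between-subject mean and SD of the vertical descent
#'   amplitude in cm.
#' @param load_effect named list mapping load (as character, e.g. "50") to
#'   \code{c(vshift, hdrift)}: vertical-amplitude shift and horizontal drift
#'   in cm applied at that load. Defaults to no effect.
#' @param noise_sd per-frame positional noise SD in cm.
#' @param seed integer master seed.
#' @return Object of class \code{"generator_params"} (a validated list).
#' @export
generator_params <- function(n_subjects = 10L,
                             loads = c(0, 50, 75),
                             reps_per_load = 3L,
                             fps = 30,
                             duration_frames = 90L,
                             amplitude_mean = c(barbell = 62, hip = 32,
                                                knee = 9, ankle = 0.5),
                             amplitude_sd = c(barbell = 9, hip = 6,
                                              knee = 2, ankle = 0.3),
                             load_effect = NULL,
                             noise_sd = 0.5,
                             seed = 0L) {
  if (is.null(load_effect))
    load_effect <- stats::setNames(
      rep(list(c(vshift = 0, hdrift = 0)), length(loads)),
      as.character(loads))
  stopifnot(n_subjects >= 1L, reps_per_load >= 1L, fps > 0,
            duration_frames >= 5L,
            all(MARKER_IDS %in% names(amplitude_mean)),
            all(MARKER_IDS %in% names(amplitude_sd)),
            all(amplitude_mean > 0), all(amplitude_sd >= 0),
            noise_sd >= 0)
  if (!all(as.character(loads) %in% names(load_effect)))
    stop("load_effect must name every load", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), loads = loads,
                 reps_per_load = as.integer(reps_per_load), fps = fps,
                 duration_frames = as.integer(duration_frames),
                 amplitude_mean = amplitude_mean[MARKER_IDS],
                 amplitude_sd = amplitude_sd[MARKER_IDS],
                 load_effect = load_effect, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "generator_params")
}

## subject-level amplitude intercepts, deterministic in (params$seed, subject)
subject_amplitudes <- function(params, subject_index) {
  with_seed(params$seed + 1000L * subject_index, {
    a <- stats::rnorm(length(MARKER_IDS), params$amplitude_mean,
                      params$amplitude_sd)
    stats::setNames(pmax(a, 0.05 * params$amplitude_mean),  # stay positive
                    MARKER_IDS)
  })
}

#' Generate one synthetic squat execution with ground truth
#'
#' @param params a \code{\link{generator_params}}.
#' @param subject subject index in 1..n_subjects.
#' @param load one of \code{params$loads}.
#' @param rep repetition index in 1..reps_per_load.
#' @return List with \code{execution} (a \code{\link{squat_execution}}) and
#'   \code{truth}: the true phase-split frame, and per marker the true
#'   noise-free maximum ascent displacement (cm).
#' @export
generate_execution <- function(params, subject, load, rep) {
  stopifnot(inherits(params, "generator_params"))
  subject <- as.integer(subject); rep <- as.integer(rep)
  if (!load %in% params$loads) stop("unknown load ", load, call. = FALSE)
  Tn <- params$duration_frames
  frames <- seq_len(Tn) - 1L
  split_i <- Tn %/% 2L               # interior minimum by construction
  eff <- params$load_effect[[as.character(load)]]
  amps <- subject_amplitudes(params, subject)
  rep_seed <- params$seed + 7919L * subject + 101L * match(load, params$loads) +
    13L * rep
  trajs <- list()
  truth_max <- numeric(length(MARKER_IDS))
  names(truth_max) <- MARKER_IDS
  noise <- with_seed(rep_seed,
                     matrix(stats::rnorm(2L * Tn * length(MARKER_IDS), 0,
                                         params$noise_sd),
                            ncol = 2L * length(MARKER_IDS)))
  for (k in seq_along(MARKER_IDS)) {
    m <- MARKER_IDS[k]
    amp <- max(amps[[m]] + eff[[1L]], 0.01)   # amplitudes stay positive
    drift <- eff[[2L]]
    ## half-cosine down over [0, split], half-cosine up over [split, T-1]
    y <- numeric(Tn)
    down <- frames <= split_i
    y[down] <- -amp / 2 * (1 - cos(pi * frames[down] / split_i))
    y[!down] <- -amp / 2 *
      (1 + cos(pi * (frames[!down] - split_i) / (Tn - 1L - split_i)))
    ## small coupled horizontal excursion, zero at start, bottom and end of
    ## the repetition (so the noise-free max ascent displacement is exactly
    ## the vertical amplitude), plus load-induced drift over the repetition
    x <- numeric(Tn)
    x[down] <- 0.1 * amps[[m]] * sin(pi * frames[down] / split_i)
    x[!down] <- -0.1 * amps[[m]] *
      sin(pi * (frames[!down] - split_i) / (Tn - 1L - split_i))
    x <- x + drift * frames / (Tn - 1L)
    ## true (noise-free) max ascent displacement: from the bottom sample to
    ## the farthest later sample
    ia <- which(frames >= split_i)
    truth_max[m] <- max(sqrt((x[ia] - x[ia[1L]])^2 + (y[ia] - y[ia[1L]])^2))
    xn <- x + noise[, 2L * k - 1L]
    yn <- y + noise[, 2L * k]
    trajs[[m]] <- marker_trajectory(m, frames, xn, yn, fps = params$fps)
  }
  ex <- squat_execution(sprintf("S%02d", subject), load, rep, trajs)
  list(execution = ex,
       truth = list(phase_split = split_i, max_displacement = truth_max))
}

#' Generate a synthetic squat cohort with a ground-truth table
#'
#' @param params a \code{\link{generator_params}}.
#' @return List with \code{dataset} (a \code{\link{squat_dataset}} passing
#'   all structural validation) and \code{truth}: a data frame of every true
#'   phase split and per-marker noise-free maximum ascent displacement.
#' @export
generate_cohort <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  execs <- list()
  truth <- list()
  for (s in seq_len(params$n_subjects)) {
    for (load in params$loads) {
      for (r in seq_len(params$reps_per_load)) {
        g <- generate_execution(params, s, load, r)
        execs[[length(execs) + 1L]] <- g$execution
        truth[[length(truth) + 1L]] <- data.frame(
          subject = g$execution$subject_id, load_pct_bw = load,
          repetition = r, marker = MARKER_IDS,
          true_phase_split = g$truth$phase_split,
          true_max_displacement_cm = unname(g$truth$max_displacement),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(dataset = squat_dataset(execs,
                               metadata = list(generator = "squathmm",
                                               seed = params$seed)),
       truth = do.call(rbind, truth))
}
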