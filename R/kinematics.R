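#' Euclidean displacement between two marker positions
#'
#' The displacement \eqn{d = \sqrt{(x_f - x_i)^2 + (y_f - y_i)^2}} between an
#' initial and a final 2D position, in centimetres.
#'
#' @param p_initial,p_final numeric length-2 vectors \code{c(x, y)} in cm.
#' @return Non-negative displacement in cm.
#' @examples
#' euclidean_displacement(c(0, 0), c(3, 4))  # 5
#' @export
euclidean_displacement <- function(p_initial, p_final) {
  check_point(p_initial); check_point(p_final)
  sqrt(sum((p_final - p_initial)^2))
}

#' Signed vertical distance between two marker positions
#'
#' \eqn{\Delta y = y_f - y_i}: positive when the marker finishes higher than
#' it started. Antisymmetric under argument swap.
#'
#' @inheritParams euclidean_displacement
#' @return Signed vertical distance in cm.
#' @export
vertical_distance <- function(p_initial, p_final) {
  check_point(p_initial); check_point(p_final)
  p_final[2L] - p_initial[2L]
}

check_point <- function(p) {
  if (!is.numeric(p) || length(p) != 2L || !all(is.finite(p)))
    stop("a point must be a finite numeric vector c(x, y)", call. = FALSE)
  invisible(p)
}

#' Split a squat execution into descent and ascent phases
#'
#' The turning point is the frame at which the reference marker reaches its
#' global vertical minimum — the bottom of the squat. Only the ascent phase
#' (from that frame to the end) enters displacement analysis and HMM
#' modelling. If several frames tie for the minimum (possible in noiseless
#' synthetic data), the first is taken.
#'
#' @param execution a \code{\link{squat_execution}}.
#' @param reference_marker marker whose y-minimum defines the split; the
#'   barbell is the natural turn-around reference, with the hip as fallback
#'   when no barbell marker was tracked.
#' @return The execution with \code{phase_split} set.
#' @export
split_phases <- function(execution, reference_marker = c("barbell", "hip",
                                                         "knee", "ankle")) {
  stopifnot(inherits(execution, "squat_execution"))
  reference_marker <- match.arg(reference_marker)
  if (!reference_marker %in% names(execution$trajectories)) {
    if (reference_marker == "barbell" && "hip" %in% names(execution$trajectories))
      reference_marker <- "hip"
    else
      stop("reference marker '", reference_marker, "' absent from execution",
           call. = FALSE)
  }
  tr <- execution$trajectories[[reference_marker]]
  imin <- which.min(tr$y)
  if (imin == 1L || imin == length(tr$y))
    stop("degenerate motion: vertical minimum at the first or last frame; ",
         "no descent-ascent shape", call. = FALSE)
  execution$phase_split <- tr$frame[imin]
  execution
}

## internal: indices (into the sample vectors) of the ascent phase
ascent_indices <- function(execution) {
  if (is.null(execution$phase_split))
    execution <- split_phases(execution)
  fr <- execution$trajectories[[1L]]$frame
  which(fr >= execution$phase_split)
}

#' Maximum displacement of a marker over a phase
#'
#' The maximum, over all frames of the phase, of the Euclidean displacement
#' from the marker's position at the first frame of the phase. This is the
#' per-repetition quantity summarised per marker and load in the study
#' design's displacement table.
#'
#' @param trajectory a \code{\link{marker_trajectory}}.
#' @param phase integer vector of sample indices into the trajectory
#'   (e.g. from the ascent split); must be non-empty and within range.
#' @return Maximum displacement in cm.
#' @export
max_displacement <- function(trajectory, phase = seq_along(trajectory$frame)) {
  stopifnot(inherits(trajectory, "marker_trajectory"))
  phase <- as.integer(phase)
  if (!length(phase) || any(phase < 1L) || any(phase > length(trajectory$frame)))
    stop("phase must be a non-empty index range within the trajectory",
         call. = FALSE)
  x <- trajectory$x[phase]; y <- trajectory$y[phase]
  max(sqrt((x - x[1L])^2 + (y - y[1L])^2))
}

#' Per-repetition maximum ascent displacements for a whole dataset
#'
#' For every execution, splits phases on the reference marker and computes
#' each marker's maximum ascent-phase displacement and net vertical distance.
#'
#' @param dataset a \code{\link{squat_dataset}}.
#' @param reference_marker passed to \code{\link{split_phases}}.
#' @return A data frame with one row per (subject, load, repetition, marker):
#'   columns \code{subject}, \code{load_pct_bw}, \code{repetition},
#'   \code{marker}, \code{max_displacement_cm}, \code{net_vertical_cm}.
#' @export
displacement_table <- function(dataset, reference_marker = "barbell") {
  stopifnot(inherits(dataset, "squat_dataset"))
  rows <- lapply(dataset$executions, function(e) {
    e <- split_phases(e, reference_marker)
    idx <- ascent_indices(e)
    do.call(rbind, lapply(e$trajectories, function(tr) {
      p0 <- c(tr$x[idx[1L]], tr$y[idx[1L]])
      pT <- c(tr$x[idx[length(idx)]], tr$y[idx[length(idx)]])
      data.frame(subject = e$subject_id, load_pct_bw = e$load_pct_bw,
                 repetition = e$repetition, marker = tr$marker_id,
                 max_displacement_cm = max_displacement(tr, idx),
                 net_vertical_cm = vertical_distance(p0, pT),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort displacement summary (per-subject means, cohort mean and SD)
#'
#' Collapses per-repetition maximum displacements to one value per subject,
#' load and marker (the mean over that subject's repetitions), then reports
#' the cohort mean and sample standard deviation (n - 1 denominator) over
#' subjects, the granularity at which the study design tabulates
#' displacements.
#'
#' @param disp either a \code{\link{squat_dataset}} or a per-repetition data
#'   frame as returned by \code{\link{displacement_table}}, or any data frame
#'   with columns \code{subject}, \code{load_pct_bw}, \code{marker} and a
#'   value column named \code{max_displacement_cm}.
#' @param ... passed to \code{displacement_table} when \code{disp} is a
#'   dataset.
#' @return A list with \code{per_subject} (data frame: subject, load, marker,
#'   value = mean over repetitions, n_reps) and \code{aggregate} (data frame:
#'   load, marker, mean, sd, n_subjects; \code{sd} is \code{NA} with a
#'   warning-free flag column \code{sd_defined = FALSE} when only one subject
#'   contributes).
#' @export
summarize_displacements <- function(disp, ...) {
  if (inherits(disp, "squat_dataset")) disp <- displacement_table(disp, ...)
  stopifnot(all(c("subject", "load_pct_bw", "marker", "max_displacement_cm")
                %in% names(disp)))
  per_subj <- stats::aggregate(
    max_displacement_cm ~ subject + load_pct_bw + marker, data = disp,
    FUN = mean)
  names(per_subj)[names(per_subj) == "max_displacement_cm"] <- "value"
  nrep <- stats::aggregate(
    max_displacement_cm ~ subject + load_pct_bw + marker, data = disp,
    FUN = length)
  per_subj$n_reps <- nrep$max_displacement_cm
  agg_mean <- stats::aggregate(value ~ load_pct_bw + marker, data = per_subj,
                               FUN = mean)
  agg_sd <- stats::aggregate(value ~ load_pct_bw + marker, data = per_subj,
                             FUN = function(v) if (length(v) > 1L) stats::sd(v)
                                               else NA_real_)
  agg_n <- stats::aggregate(value ~ load_pct_bw + marker, data = per_subj,
                            FUN = length)
  aggregate <- data.frame(load_pct_bw = agg_mean$load_pct_bw,
                          marker = agg_mean$marker,
                          mean = agg_mean$value, sd = agg_sd$value,
                          n_subjects = agg_n$value,
                          sd_defined = agg_n$value > 1L,
                          stringsAsFactors = FALSE)
  ord <- order(aggregate$marker, aggregate$load_pct_bw)
  list(per_subject = per_subj, aggregate = aggregate[ord, , drop = FALSE])
}

#' Reference per-volunteer maximum displacements
#'
#' Loads the bundled table of maximum ascent-phase marker displacements (cm)
#' for a ten-volunteer back-squat cohort at 0, 50 and 75 %BW loads — the
#' reference values against which the kinematics summaries are checked.
#'
#' @return Long-format data frame with columns \code{subject},
#'   \code{load_pct_bw}, \code{marker}, \code{max_displacement_cm}.
#' @export
reference_displacements <- function() {
  path <- system.file("extdata", "squat_max_displacements.csv",
                      package = "squathmm", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
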