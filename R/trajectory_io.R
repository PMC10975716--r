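#' @keywords internal
"_PACKAGE"

MARKER_IDS <- c("barbell", "hip", "knee", "ankle")

#' Marker trajectory
#'
#' A single marker's time-ordered 2D positions (in centimetres) for one squat
#' execution, sampled at a fixed frame rate. Coordinates follow the video
#' convention of the study design: x increases left to right, y increases
#' bottom to top, origin at the marker's per-repetition start position (or raw
#' lab coordinates if the caller has not re-zeroed; see
#' \code{\link{read_squat_csv}}'s \code{normalize} flag).
#'
#' @param marker_id one of \code{"barbell"}, \code{"hip"}, \code{"knee"},
#'   \code{"ankle"}.
#' @param frame integer vector of frame indices, strictly increasing with no
#'   gaps (consecutive integers); 0-based by convention.
#' @param x,y numeric coordinate vectors in cm, same length as \code{frame}.
#' @param fps frames per second (default 30, the study's capture rate).
#' @return An object of class \code{"marker_trajectory"}: a list with elements
#'   \code{marker_id}, \code{frame}, \code{x}, \code{y}, \code{fps}.
#' @examples
#' tr <- marker_trajectory("hip", frame = 0:3, x = rep(0, 4), y = c(0, -2, -2, 0))
#' tr
#' @export
marker_trajectory <- function(marker_id, frame, x, y, fps = 30) {
  marker_id <- match.arg(marker_id, MARKER_IDS)
  frame <- as.integer(frame)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(frame) < 2L)
    stop("a marker trajectory needs at least 2 samples", call. = FALSE)
  if (length(x) != length(frame) || length(y) != length(frame))
    stop("frame, x and y must have equal length", call. = FALSE)
  if (anyNA(frame) || any(diff(frame) != 1L))
    stop("frame indices must be strictly increasing consecutive integers (no gaps)",
         call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("coordinates must be finite", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("fps must be a single positive number", call. = FALSE)
  structure(list(marker_id = marker_id, frame = frame, x = x, y = y, fps = fps),
            class = "marker_trajectory")
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat(sprintf("<marker_trajectory> %s: %d frames [%d..%d] @ %g fps\n",
              x$marker_id, length(x$frame), x$frame[1L],
              x$frame[length(x$frame)], x$fps))
  invisible(x)
}

#' @export
length.marker_trajectory <- function(x) length(x$frame)

#' Squat execution
#'
#' One repetition of the back squat: a subject, a barbell load expressed as a
#' percentage of body weight, a repetition index, and the four marker
#' trajectories. All trajectories must share the same frame range and frame
#' rate. \code{phase_split} is the frame index of the descent-to-ascent
#' turning point; it is \code{NULL} until computed by
#' \code{\link{split_phases}}.
#'
#' @param subject_id character scalar identifying the lifter.
#' @param load_pct_bw barbell load in percent of body weight (\eqn{\ge 0};
#'   study loads are 0, 50, 75).
#' @param repetition integer repetition index \eqn{\ge 1}.
#' @param trajectories named list of \code{\link{marker_trajectory}} objects,
#'   names matching their \code{marker_id}s.
#' @param phase_split optional frame index of the turning point, strictly
#'   inside the shared frame range.
#' @return An object of class \code{"squat_execution"}.
#' @export
squat_execution <- function(subject_id, load_pct_bw, repetition, trajectories,
                            phase_split = NULL) {
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id))
    stop("subject_id must be a non-empty string", call. = FALSE)
  load_pct_bw <- as.numeric(load_pct_bw)
  if (length(load_pct_bw) != 1L || !is.finite(load_pct_bw) || load_pct_bw < 0)
    stop("load_pct_bw must be a single number >= 0", call. = FALSE)
  repetition <- as.integer(repetition)
  if (length(repetition) != 1L || is.na(repetition) || repetition < 1L)
    stop("repetition must be a single integer >= 1", call. = FALSE)
  if (!length(trajectories))
    stop("at least one marker trajectory is required", call. = FALSE)
  ok <- vapply(trajectories, inherits, logical(1), "marker_trajectory")
  if (!all(ok))
    stop("trajectories must all be marker_trajectory objects", call. = FALSE)
  ids <- vapply(trajectories, `[[`, character(1), "marker_id")
  if (anyDuplicated(ids))
    stop("duplicate marker in execution", call. = FALSE)
  names(trajectories) <- ids
  fr0 <- trajectories[[1L]]$frame
  fps0 <- trajectories[[1L]]$fps
  for (tr in trajectories) {
    if (!identical(tr$frame, fr0))
      stop("all trajectories of an execution must share the same frame range",
           call. = FALSE)
    if (tr$fps != fps0)
      stop("all trajectories of an execution must share fps", call. = FALSE)
  }
  if (!is.null(phase_split)) {
    phase_split <- as.integer(phase_split)
    if (phase_split <= fr0[1L] || phase_split >= fr0[length(fr0)])
      stop("phase_split must lie strictly inside the frame range", call. = FALSE)
  }
  structure(list(subject_id = subject_id, load_pct_bw = load_pct_bw,
                 repetition = repetition, trajectories = trajectories,
                 phase_split = phase_split),
            class = "squat_execution")
}

#' @export
print.squat_execution <- function(x, ...) {
  cat(sprintf("<squat_execution> subject %s, load %g%%BW, rep %d: %s; %d frames%s\n",
              x$subject_id, x$load_pct_bw, x$repetition,
              paste(names(x$trajectories), collapse = ","),
              length(x$trajectories[[1L]]$frame),
              if (is.null(x$phase_split)) "" else
                sprintf(", phase split @ %d", x$phase_split)))
  invisible(x)
}

#' Squat trajectory dataset
#'
#' A collection of \code{\link{squat_execution}}s with unique
#' (subject, load, repetition) keys plus free-form metadata.
#'
#' @param executions list of \code{squat_execution} objects.
#' @param metadata named list of free-form capture notes.
#' @return An object of class \code{"squat_dataset"}.
#' @export
squat_dataset <- function(executions = list(), metadata = list()) {
  ok <- vapply(executions, inherits, logical(1), "squat_execution")
  if (length(executions) && !all(ok))
    stop("executions must be squat_execution objects", call. = FALSE)
  keys <- vapply(executions, function(e)
    paste(e$subject_id, e$load_pct_bw, e$repetition, sep = "\r"), character(1))
  if (anyDuplicated(keys))
    stop("duplicate (subject, load, repetition) in dataset", call. = FALSE)
  structure(list(executions = executions, metadata = metadata),
            class = "squat_dataset")
}

#' @export
print.squat_dataset <- function(x, ...) {
  subs <- unique(vapply(x$executions, `[[`, character(1), "subject_id"))
  loads <- sort(unique(vapply(x$executions, `[[`, numeric(1), "load_pct_bw")))
  cat(sprintf("<squat_dataset> %d executions, %d subjects, loads {%s} %%BW\n",
              length(x$executions), length(subs),
              paste(loads, collapse = ", ")))
  invisible(x)
}

#' @export
length.squat_dataset <- function(x) length(x$executions)

## internal: stable lookup of executions
dataset_keys <- function(dataset) {
  data.frame(
    subject = vapply(dataset$executions, `[[`, character(1), "subject_id"),
    load = vapply(dataset$executions, `[[`, numeric(1), "load_pct_bw"),
    repetition = vapply(dataset$executions, `[[`, integer(1), "repetition"),
    stringsAsFactors = FALSE)
}

#' Read a marker-trajectory dataset from long-format CSV
#'
#' The interchange dialect is a long-format CSV with header
#' \code{subject,load_pct_bw,repetition,marker,frame,x_cm,y_cm}, UTF-8, '.'
#' decimal separator, one row per marker per frame. Units are centimetres; y
#' increases upward. The reader validates all structural invariants (no
#' duplicate or gapped frames, consistent frame ranges within an execution).
#'
#' @param path CSV file path.
#' @param fps frames per second of the capture (default 30).
#' @param normalize if \code{TRUE}, re-zero every trajectory to its first
#'   sample, for files exported in raw lab coordinates rather than the
#'   per-repetition marker-start origin.
#' @return A \code{\link{squat_dataset}}.
#' @seealso \code{\link{write_squat_csv}}
#' @export
read_squat_csv <- function(path, fps = 30, normalize = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject", "load_pct_bw", "repetition", "marker", "frame",
                "x_cm", "y_cm")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (!nrow(df)) return(squat_dataset())
  key4 <- paste(df$subject, df$load_pct_bw, df$repetition, df$marker, df$frame,
                sep = "\r")
  if (anyDuplicated(key4))
    stop("duplicate (subject, load, repetition, marker, frame) rows",
         call. = FALSE)
  execs <- list()
  splits <- split(df, paste(df$subject, df$load_pct_bw, df$repetition, sep = "\r"),
                  drop = TRUE)
  for (ed in splits) {
    trajs <- lapply(split(ed, ed$marker, drop = TRUE), function(md) {
      md <- md[order(md$frame), , drop = FALSE]
      if (any(diff(md$frame) != 1L))
        stop("non-consecutive frames for subject ", md$subject[1L],
             " marker ", md$marker[1L], call. = FALSE)
      x <- md$x_cm; y <- md$y_cm
      if (isTRUE(normalize)) { x <- x - x[1L]; y <- y - y[1L] }
      marker_trajectory(md$marker[1L], md$frame, x, y, fps = fps)
    })
    execs[[length(execs) + 1L]] <- squat_execution(
      as.character(ed$subject[1L]), ed$load_pct_bw[1L], ed$repetition[1L], trajs)
  }
  ord <- order(vapply(execs, `[[`, character(1), "subject_id"),
               vapply(execs, `[[`, numeric(1), "load_pct_bw"),
               vapply(execs, `[[`, integer(1), "repetition"))
  squat_dataset(execs[ord], metadata = list(source = path, units = "cm"))
}

#' Write a marker-trajectory dataset to long-format CSV
#'
#' Inverse of \code{\link{read_squat_csv}}; coordinates are written with 9
#' significant digits so a round trip preserves them to well within 1e-6
#' relative tolerance.
#'
#' @param dataset a \code{\link{squat_dataset}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_squat_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "squat_dataset"))
  rows <- lapply(dataset$executions, function(e) {
    do.call(rbind, lapply(e$trajectories, function(tr) {
      data.frame(subject = e$subject_id, load_pct_bw = e$load_pct_bw,
                 repetition = e$repetition, marker = tr$marker_id,
                 frame = tr$frame,
                 x_cm = signif(tr$x, 9), y_cm = signif(tr$y, 9),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = character(), load_pct_bw = numeric(),
               repetition = integer(), marker = character(), frame = integer(),
               x_cm = numeric(), y_cm = numeric())
  tryCatch(utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}
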