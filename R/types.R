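#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule records the start and end time of every reconstructed
#' frame, in minutes post-injection. Frames must be sorted, non-overlapping
#' and strictly positive in duration.
#'
#' @param start Numeric vector of frame start times (minutes post-injection).
#' @param end Numeric vector of frame end times (minutes post-injection).
#' @return An object of class `frame_schedule`: a data frame with columns
#'   `start` and `end` (minutes).
#' @examples
#' frame_schedule(c(0, 1, 2), c(1, 2, 5))
#' @export
frame_schedule <- function(start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != length(end) || length(start) < 1L)
    stop("start and end must have equal length >= 1")
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stop("frame times must be finite")
  if (any(start < 0))
    stop("frame times must be >= 0")
  if (any(end <= start))
    stop("each frame end must exceed its start")
  ord <- order(start)
  start <- start[ord]; end <- end[ord]
  if (length(start) > 1L && any(start[-1L] < end[-length(end)] - 1e-9))
    stop("frames must be non-overlapping")
  structure(data.frame(start = start, end = end),
            class = c("frame_schedule", "data.frame"))
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, %.4g-%.4g min\n",
              nrow(x), x$start[1L], x$end[nrow(x)]))
  invisible(x)
}

#' Number of frames in a schedule
#' @param schedule A [frame_schedule()].
#' @return Integer frame count.
#' @export
n_frames <- function(schedule) nrow(schedule)

#' Frame mid-times and durations
#' @param schedule A [frame_schedule()].
#' @return Numeric vector in minutes.
#' @export
frame_mid_times <- function(schedule) (schedule$start + schedule$end) / 2

#' @rdname frame_mid_times
#' @export
frame_durations <- function(schedule) schedule$end - schedule$start

#' Regional time-activity curve
#'
#' Tracer concentration of a region at each frame, indexed by frame
#' mid-time. Mid-times must be strictly increasing with positive durations.
#'
#' @param mid_times Frame mid-times, minutes post-injection.
#' @param durations Frame durations, minutes.
#' @param values Activity concentration per frame, kBq/mL.
#' @return An object of class `tac`.
#' @export
tac <- function(mid_times, durations, values) {
  mid_times <- as.numeric(mid_times)
  durations <- as.numeric(durations)
  values <- as.numeric(values)
  n <- length(mid_times)
  if (length(durations) != n || length(values) != n || n < 1L)
    stop("mid_times, durations and values must have equal length >= 1")
  if (any(!is.finite(mid_times)) || any(!is.finite(durations)) ||
      any(!is.finite(values)))
    stop("tac fields must be finite")
  if (n > 1L && any(diff(mid_times) <= 0))
    stop("mid_times must be strictly increasing")
  if (any(durations <= 0))
    stop("durations must be > 0")
  structure(list(mid_times = mid_times, durations = durations,
                 values = values), class = "tac")
}

#' Build a TAC on a frame schedule
#' @param schedule A [frame_schedule()].
#' @param values Activity per frame, kBq/mL.
#' @return A [tac()].
#' @export
tac_on_schedule <- function(schedule, values) {
  tac(frame_mid_times(schedule), frame_durations(schedule), values)
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf(
    "Time-activity curve: %d frames, %.3g-%.3g min, peak %.4g kBq/mL\n",
    length(x$values), x$mid_times[1L], x$mid_times[length(x$mid_times)],
    max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(mid_time = x$mid_times, duration = x$durations,
             value = x$values)
}

#' @export
length.tac <- function(x) length(x$values)

#' Arterial plasma input function
#'
#' Plasma tracer concentration over time, optionally carrying a population
#' parent-fraction curve describing the proportion of plasma activity that
#' is unmetabolized parent compound.
#'
#' @param times Sample times, minutes post-injection, strictly increasing
#'   from >= 0.
#' @param total_plasma Total plasma concentration, kBq/mL, >= 0.
#' @param parent_fraction Fraction of unmetabolized parent compound per
#'   sample, in `[0, 1]`. Default 1 (no metabolite correction pending).
#' @return An object of class `input_function`.
#' @seealso [apply_parent_fraction()], [logan_plasma()]
#' @export
input_function <- function(times, total_plasma,
                           parent_fraction = rep(1, length(times))) {
  times <- as.numeric(times)
  total_plasma <- as.numeric(total_plasma)
  parent_fraction <- as.numeric(parent_fraction)
  n <- length(times)
  if (length(total_plasma) != n || length(parent_fraction) != n || n < 2L)
    stop("times, total_plasma and parent_fraction must have equal length >= 2")
  if (any(!is.finite(times)) || any(!is.finite(total_plasma)) ||
      any(!is.finite(parent_fraction)))
    stop("input function fields must be finite")
  if (times[1L] < 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing from >= 0")
  if (any(total_plasma < 0))
    stop("plasma concentrations must be >= 0")
  if (any(parent_fraction < 0 | parent_fraction > 1))
    stop("parent_fraction must lie in [0, 1]")
  structure(list(times = times, total_plasma = total_plasma,
                 parent_fraction = parent_fraction),
            class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf(
    "Input function: %d samples, %.3g-%.3g min, peak %.4g kBq/mL%s\n",
    length(x$times), x$times[1L], x$times[length(x$times)],
    max(x$total_plasma),
    if (all(x$parent_fraction == 1)) "" else " (parent fraction pending)"))
  invisible(x)
}

#' Injected dose and body weight for SUV normalization
#'
#' @param injected_dose Injected activity, MBq, > 0.
#' @param body_weight Body weight, kg, > 0.
#' @return An object of class `dose_record`.
#' @export
dose_record <- function(injected_dose, body_weight) {
  if (!is.numeric(injected_dose) || length(injected_dose) != 1L ||
      !is.finite(injected_dose) || injected_dose <= 0)
    stop("injected_dose must be a single positive number (MBq)")
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      !is.finite(body_weight) || body_weight <= 0)
    stop("body_weight must be a single positive number (kg)")
  structure(list(injected_dose = injected_dose, body_weight = body_weight),
            class = "dose_record")
}
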