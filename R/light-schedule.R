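#' Illumination patterns and intensity levels
#'
#' The optogenetic stimulation grid uses three temporal patterns --
#' `"Su"` (sustained illumination), `"Pe"` (periodic: 5 min light followed by
#' 5 min darkness, repeated) and `"Pu"` (pulsed: a single 5-min illumination
#' followed by darkness) -- at three light intensity levels, encoded by their
#' nominal power in mW/cm2 as `"005"`, `"010"` and `"025"`.
#'
#' @return Character vector of valid codes.
#' @export
light_patterns <- function() c("Su", "Pe", "Pu")

#' @rdname light_patterns
#' @export
light_intensities <- function() c("005", "010", "025")

#' Build a piecewise on/off light schedule
#'
#' Constructs the illumination timeline for one stimulation regime as an
#' ordered set of contiguous on/off segments covering `[0, duration_min]`.
#' A dark control is represented by `duration_min = 0` (a single degenerate
#' off-segment).
#'
#' @param pattern One of `"Su"`, `"Pe"`, `"Pu"` (see [light_patterns()]).
#' @param intensity One of `"005"`, `"010"`, `"025"`.
#' @param duration_min Total schedule duration in minutes; one of 0, 10, 20, 30.
#'
#' @return An object of class `light_schedule`: a list with `pattern`,
#'   `intensity`, `duration` and a `segments` tibble
#'   (`t_start`, `t_end`, `light_on`).
#' @examples
#' light_schedule("Pe", "010", 30)
#' @export
light_schedule <- function(pattern, intensity, duration_min = 30) {
  if (length(pattern) != 1 || !pattern %in% light_patterns()) {
    abort(
      paste0("`pattern` must be one of ", paste(light_patterns(), collapse = ", ")),
      class = "optophos_validation_error"
    )
  }
  if (length(intensity) != 1 || !intensity %in% light_intensities()) {
    abort(
      paste0("`intensity` must be one of ", paste(light_intensities(), collapse = ", ")),
      class = "optophos_validation_error"
    )
  }
  if (length(duration_min) != 1 || !is.numeric(duration_min) ||
      !duration_min %in% c(0, 10, 20, 30)) {
    abort("`duration_min` must be one of 0, 10, 20, 30",
      class = "optophos_validation_error"
    )
  }

  if (duration_min == 0) {
    segments <- tibble(t_start = 0, t_end = 0, light_on = FALSE)
  } else if (pattern == "Su") {
    segments <- tibble(t_start = 0, t_end = duration_min, light_on = TRUE)
  } else if (pattern == "Pe") {
    starts <- seq(0, duration_min - 5, by = 5)
    segments <- tibble(
      t_start = starts,
      t_end = starts + 5,
      light_on = rep_len(c(TRUE, FALSE), length(starts))
    )
  } else { # Pu
    segments <- tibble(
      t_start = c(0, 5),
      t_end = c(5, duration_min),
      light_on = c(TRUE, FALSE)
    )
    if (duration_min == 5) segments <- segments[1, ]
  }

  structure(
    list(
      pattern = pattern, intensity = intensity,
      duration = duration_min, segments = segments
    ),
    class = "light_schedule"
  )
}

#' Dark (no illumination) control schedule
#'
#' @param duration_min Duration of the off-segment in minutes.
#' @return A `light_schedule` whose single segment is off.
#' @export
dark_schedule <- function(duration_min = 30) {
  structure(
    list(
      pattern = "none", intensity = "none", duration = duration_min,
      segments = tibble(t_start = 0, t_end = duration_min, light_on = FALSE)
    ),
    class = "light_schedule"
  )
}

#' All 27 stimulation schedules of the full factorial design
#'
#' @param duration_min Duration each regime is simulated to (the within-regime
#'   time series is sampled from a single trajectory).
#' @return Named list of `light_schedule` objects, one per pattern x intensity,
#'   names like `"Su025"`.
#' @export
all_light_schedules <- function(duration_min = 30) {
  grid <- expand.grid(
    intensity = light_intensities(), pattern = light_patterns(),
    stringsAsFactors = FALSE
  )
  out <- purrr::map2(
    grid$pattern, grid$intensity,
    ~ light_schedule(.x, .y, duration_min)
  )
  names(out) <- paste0(grid$pattern, grid$intensity)
  out
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf(
    "<light_schedule> pattern=%s intensity=%s duration=%g min\n",
    x$pattern, x$intensity, x$duration
  ))
  print(x$segments)
  invisible(x)
}

#' Fraction of time the light is on at given times
#'
#' Indicator of illumination, vectorised over `times`. Segment boundaries
#' belong to the segment that starts there (right-open intervals), except the
#' final boundary which belongs to the last segment.
#'
#' @param schedule A `light_schedule`.
#' @param times Numeric vector of times (minutes).
#' @return Logical vector, `TRUE` where the light is on.
#' @export
light_on_at <- function(schedule, times) {
  seg <- schedule$segments
  idx <- findInterval(times, seg$t_start, rightmost.closed = FALSE)
  idx[idx < 1] <- 1L
  idx[idx > nrow(seg)] <- nrow(seg)
  seg$light_on[idx] & times <= schedule$duration & times >= 0
}
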