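#' Build a photostimulation schedule
#'
#' A stimulus schedule is an ordered sequence of light-off/light-on segments
#' with durations in seconds, plus the boundaries of the sequential videos
#' recorded by the acquisition script.
#'
#' Two named protocols are provided:
#' \describe{
#'   \item{`"standard"`}{Three sequential videos: a 5-min pre-stimulus video,
#'     a 6-min stimulus video with three 10-s blue-light pulses at 100%
#'     intensity starting at the 60, 160 and 260 s mark of that video, and a
#'     5-min post-stimulus video; 16 min in total.}
#'   \item{`"serial"`}{5 min off, then twenty cycles of 10 s on / 90 s off,
#'     then 5 min off; 2600 s in total, used to study sensitisation to
#'     repeated stimulation.}
#' }
#'
#' A custom schedule is built from a data frame of segments with columns
#' `label` (`"off"`/`"on"`), `duration` (s) and optionally `intensity`
#' (percent, default 100 for on-segments).
#'
#' @param kind `"standard"`, `"serial"`, or `"custom"`.
#' @param segments For `kind = "custom"`, the segment data frame.
#' @param video_boundaries For `kind = "custom"`, optional numeric vector of
#'   video start/end times in seconds (must start at 0 and end at the total
#'   duration).
#'
#' @return A `stim_schedule` object: list with `segments` (tibble with
#'   `label`, `t_start`, `t_end`, `duration`, `intensity`), `pulses` (tibble
#'   with `pulse`, `t_start`, `t_end`), `video_boundaries`, and
#'   `total_duration` (s).
#' @export
build_schedule <- function(kind = c("standard", "serial", "custom"),
                           segments = NULL, video_boundaries = NULL) {
  kind <- match.arg(kind)
  if (kind == "standard") {
    seg <- tibble::tibble(
      label = c("off", "on", "off", "on", "off", "on", "off"),
      duration = c(300 + 60, 10, 90, 10, 90, 10, 90 + 300),
      intensity = c(0, 100, 0, 100, 0, 100, 0)
    )
    vb <- c(0, 300, 660, 960)
  } else if (kind == "serial") {
    seg <- tibble::tibble(
      label = c("off", rep(c("on", "off"), 20)),
      duration = c(300, rep(c(10, 90), 20)),
      intensity = c(0, rep(c(100, 0), 20))
    )
    # trailing 90 s of the last cycle runs into the final 5-min off period
    seg$duration[nrow(seg)] <- 90 + 300
    vb <- c(0, 2600)
  } else {
    stopifnot(is.data.frame(segments), all(c("label", "duration") %in% names(segments)))
    seg <- tibble::as_tibble(segments)
    if (!"intensity" %in% names(seg)) {
      seg$intensity <- ifelse(seg$label == "on", 100, 0)
    }
    vb <- video_boundaries
  }
  if (any(seg$duration <= 0)) stop("segment durations must be > 0", call. = FALSE)
  if (!all(seg$label %in% c("off", "on"))) {
    stop("segment labels must be \"off\" or \"on\"", call. = FALSE)
  }
  seg$t_end <- cumsum(seg$duration)
  seg$t_start <- seg$t_end - seg$duration
  total <- seg$t_end[nrow(seg)]
  if (is.null(vb)) vb <- c(0, total)
  if (vb[1] != 0 || abs(vb[length(vb)] - total) > 1e-9) {
    stop("video boundaries must span [0, total duration]", call. = FALSE)
  }
  on <- seg[seg$label == "on", ]
  if (nrow(on) > 1) {
    if (any(on$t_start[-1] < on$t_end[-nrow(on)])) {
      stop("pulses overlap", call. = FALSE)
    }
  }
  pulses <- tibble::tibble(
    pulse = seq_len(nrow(on)),
    t_start = on$t_start, t_end = on$t_end
  )
  structure(
    list(
      segments = seg[, c("label", "t_start", "t_end", "duration", "intensity")],
      pulses = pulses,
      video_boundaries = vb,
      total_duration = total
    ),
    class = "stim_schedule"
  )
}

#' @exportS3Method base::print
print.stim_schedule <- function(x, ...) {
  cat(sprintf(
    "<stim_schedule> %g s total, %d pulse(s), %d video(s)\n",
    x$total_duration, nrow(x$pulses), length(x$video_boundaries) - 1L
  ))
  invisible(x)
}

#' Is the light on at the given times?
#'
#' @param schedule A `stim_schedule`.
#' @param t Numeric vector of times in seconds. Segments are half-open
#'   `[t_start, t_end)`.
#' @return Logical vector.
#' @export
light_on <- function(schedule, t) {
  on <- schedule$pulses
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(on))) {
    out <- out | (t >= on$t_start[i] & t < on$t_end[i])
  }
  out
}
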