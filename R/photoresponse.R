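#' Per-well motion-mode fractions over time
#'
#' At each time point in each well, the number of tracked worms in each
#' motion mode is divided by the total number of tracked worms at that time
#' point in that well. Time points with zero tracked worms are undefined
#' and omitted (not zero). Bad wells are excluded.
#'
#' @param tracks Tibble with `well`, `t`, `mode` (and optionally `bad`).
#'   Rows with `NA` mode (undefined frames) are ignored.
#' @param digits Time stamps are rounded to this many digits to form the
#'   common time base.
#' @return Tibble with `well`, `t`, `n_tracked`, `f_fw`, `f_bw`, `f_st`.
#' @export
mode_fractions <- function(tracks, digits = 6) {
  if ("bad" %in% names(tracks)) {
    tracks <- dplyr::filter(tracks, !.data$bad)
  }
  tracks |>
    dplyr::filter(!is.na(.data$mode)) |>
    dplyr::mutate(t = round(.data$t, digits)) |>
    dplyr::group_by(.data$well, .data$t) |>
    dplyr::summarise(
      n_tracked = dplyr::n(),
      f_fw = mean(.data$mode == "fw"),
      f_bw = mean(.data$mode == "bw"),
      f_st = mean(.data$mode == "st"),
      .groups = "drop"
    )
}

#' Bootstrap-aggregated motion-mode fraction curves
#'
#' Averages the per-well fraction curves across wells and attaches a 95%
#' confidence interval from a nonparametric bootstrap: wells are resampled
#' with replacement `n_boot` times and the 2.5/97.5 percentiles of the
#' resampled means taken at every time point.
#'
#' @param series Output of [mode_fractions()].
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the resampling.
#' @param conf Confidence level.
#' @return A `photoresponse_agg` tibble: `t`, `mode`, `mean`, `lo`, `hi`,
#'   `n_wells`.
#' @export
aggregate_bootstrap <- function(series, n_boot = 1000, seed = 0,
                                conf = 0.95) {
  wells <- unique(series$well)
  if (length(wells) < 2) {
    stop("bootstrap aggregation requires at least 2 wells", call. = FALSE)
  }
  set.seed(seed)
  ts <- sort(unique(series$t))
  alpha <- (1 - conf) / 2
  out <- list()
  idx <- matrix(sample.int(length(wells), n_boot * length(wells),
                           replace = TRUE),
                nrow = n_boot)
  for (mode in MOTION_MODES) {
    col <- paste0("f_", mode)
    Wm <- matrix(NA_real_, length(wells), length(ts))
    Wm[cbind(match(series$well, wells), match(series$t, ts))] <- series[[col]]
    mean_curve <- colMeans(Wm, na.rm = TRUE)
    boot <- matrix(NA_real_, n_boot, length(ts))
    for (b in seq_len(n_boot)) {
      boot[b, ] <- colMeans(Wm[idx[b, ], , drop = FALSE], na.rm = TRUE)
    }
    qs <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE, names = FALSE)
    out[[mode]] <- tibble::tibble(
      t = ts, mode = mode, mean = mean_curve,
      lo = qs[1, ], hi = qs[2, ],
      n_wells = colSums(!is.na(Wm))
    )
  }
  res <- dplyr::bind_rows(out)
  res$mode <- factor(res$mode, levels = MOTION_MODES)
  class(res) <- c("photoresponse_agg", class(res))
  res
}

#' @export
autoplot.photoresponse_agg <- function(object, schedule = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$t, y = .data$mean,
                                    colour = .data$mode, fill = .data$mode))
  if (!is.null(schedule) && nrow(schedule$pulses)) {
    p <- p + ggplot2::geom_rect(
      data = schedule$pulses,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end),
      ymin = -Inf, ymax = Inf, fill = "lightblue", alpha = 0.4,
      inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "fraction of worms",
                  colour = "mode", fill = "mode") +
    ggplot2::ylim(0, 1)
}

#' Downsample per-worm mode series to the prevalent mode
#'
#' Divides each worm's mode series into nonoverlapping `window`-second
#' intervals and outputs the prevalent (modal) mode in each, i.e. a 0.5 Hz
#' series for the default 2 s window. Ties are resolved conservatively with
#' priority `st` > `fw` > `bw`. Windows in which every frame is undefined
#' yield an undefined sample.
#'
#' @param tracks Tibble with `well`, `worm_id` (or `track_id`), `t`,
#'   `mode`.
#' @param window Window length in seconds (must cover a whole number of
#'   frames).
#' @return Tibble with `well`, `worm_id`, `t` (window start), `mode`.
#' @export
downsample_prevalent <- function(tracks, window = 2) {
  id_col <- if ("worm_id" %in% names(tracks)) "worm_id" else "track_id"
  tie_order <- c("st", "fw", "bw")
  tracks |>
    dplyr::mutate(win = floor(.data$t / window) * window) |>
    dplyr::group_by(.data$well, .data[[id_col]], .data$win) |>
    dplyr::summarise(
      mode = {
        tab <- table(factor(.data$mode, levels = tie_order))
        if (sum(tab) == 0) NA_character_ else
          names(tab)[which.max(tab)] # which.max takes the first max: st > fw > bw
      },
      .groups = "drop"
    ) |>
    dplyr::rename(t = "win", worm_id = dplyr::all_of(id_col)) |>
    dplyr::mutate(mode = factor(.data$mode, levels = MOTION_MODES))
}

#' Per-pulse response deltas
#'
#' For each stimulus pulse, the difference between the mean aggregated
#' fraction in the 10 s window just before the end of the pulse,
#' `(end - w, end]` (the stimulated level), and the 10 s window just after
#' it, `(end, end + w]` (the post-stimulus relaxation), per motion mode: the
#' stimulus-evoked change, positive for an escape response in the forward
#' mode. Pulses whose windows extend past the recording are skipped with a
#' warning.
#'
#' @param agg A `photoresponse_agg` (or any tibble with `t`, `mode`,
#'   `mean`).
#' @param schedule The `stim_schedule`.
#' @param window Window length in seconds.
#' @return Tibble with `pulse`, `mode`, `delta`.
#' @export
pulse_response_delta <- function(agg, schedule, window = 10) {
  out <- list()
  t_max <- max(agg$t); t_min <- min(agg$t)
  for (i in seq_len(nrow(schedule$pulses))) {
    e <- schedule$pulses$t_end[i]
    if (e - window < t_min - 1e-9 || e + window > t_max + 1e-9) {
      warning("pulse ", i, " skipped: window extends past the recording")
      next
    }
    for (mode in MOTION_MODES) {
      after <- agg$mean[agg$mode == mode & agg$t > e & agg$t <= e + window]
      before <- agg$mean[agg$mode == mode & agg$t > e - window & agg$t <= e]
      out[[length(out) + 1]] <- tibble::tibble(
        pulse = i, mode = mode,
        delta = mean(before, na.rm = TRUE) - mean(after, na.rm = TRUE)
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(pulse = integer(), mode = character(),
                          delta = numeric()))
  }
  res <- dplyr::bind_rows(out)
  res$mode <- factor(res$mode, levels = MOTION_MODES)
  res
}

#' Baseline shift between the start and end of a recording
#'
#' Difference of the mean aggregated fraction in each motion mode between
#' the final `window` seconds and the initial `window` seconds (default
#' 5 min each), quantifying e.g. fatigue after serial photostimulation.
#'
#' @param agg A `photoresponse_agg` (or tibble with `t`, `mode`, `mean`).
#' @param schedule The `stim_schedule` (for the total duration).
#' @param window Window length in seconds.
#' @return Tibble with `mode`, `shift`.
#' @export
baseline_shift <- function(agg, schedule, window = 300) {
  total <- schedule$total_duration
  if (total < 2 * window) {
    stop("recording shorter than two baseline windows", call. = FALSE)
  }
  purrr::map_dfr(MOTION_MODES, function(mode) {
    first <- agg$mean[agg$mode == mode & agg$t < window]
    last <- agg$mean[agg$mode == mode & agg$t >= total - window]
    tibble::tibble(
      mode = mode,
      shift = mean(last, na.rm = TRUE) - mean(first, na.rm = TRUE)
    )
  })
}
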