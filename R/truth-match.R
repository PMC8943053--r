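#' Match tracked detections to simulator ground truth
#'
#' For validation studies on synthetic sessions: each detection is
#' attributed to the truth objects whose body actually falls inside its
#' segmentation mask (worms by their midline points, debris by its centre).
#' A detection touching only worms is `"worm"`, only debris `"nonworm"`,
#' both `"mixed"`, neither `"none"`. Tracks are then classified by the
#' dominant attribution of their detections; tracks without a dominant
#' attribution (e.g. fragments from worm-debris collisions) are
#' `"ambiguous"`.
#'
#' @param tracks Tracks tibble with `track_id`, `frame`, masks and boxes.
#' @param truth The `truth` tibble of a [simulate_session()].
#' @param dominance Minimum fraction of detections with a single
#'   attribution for a track to get its class.
#' @return List with `detections` (tracks + `truth_match` column) and
#'   `tracks` (per-track tibble: `track_id`, `n`, `truth_class`, plus
#'   `is_worm`/`worm_probability_median` when present).
#' @export
match_tracks_to_truth <- function(tracks, truth, dominance = 0.8) {
  worm_truth <- truth[truth$label == "worm", ]
  deb_truth <- truth[truth$label == "nonworm", ]
  n <- nrow(tracks)
  res <- character(n)
  for (i in seq_len(n)) {
    f <- tracks$frame[i]
    m <- tracks$mask[[i]]
    x0 <- tracks$x_min[i]; y0 <- tracks$y_min[i]
    in_mask <- function(px, py) {
      r <- round(py) - y0 + 1
      cc <- round(px) - x0 + 1
      ok <- r >= 1 & r <= nrow(m) & cc >= 1 & cc <= ncol(m)
      out <- logical(length(px))
      out[ok] <- m[cbind(r[ok], cc[ok])]
      out
    }
    has_worm <- FALSE
    wt <- worm_truth[worm_truth$frame == f, ]
    for (k in seq_len(nrow(wt))) {
      ml <- wt$midline[[k]]
      if (!is.null(ml) && any(in_mask(ml[, 1], ml[, 2]))) {
        has_worm <- TRUE
        break
      }
    }
    dt <- deb_truth[deb_truth$frame == f, ]
    has_deb <- nrow(dt) > 0 && any(in_mask(dt$x, dt$y))
    res[i] <- if (has_worm && has_deb) "mixed" else if (has_worm) "worm" else
      if (has_deb) "nonworm" else "none"
  }
  det <- dplyr::mutate(tracks, truth_match = res)
  per_track <- det |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      f_worm = mean(.data$truth_match == "worm"),
      f_nonworm = mean(.data$truth_match == "nonworm"),
      dplyr::across(dplyr::any_of(c("worm_probability_median", "is_worm")),
                    dplyr::first),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      truth_class = dplyr::case_when(
        .data$f_worm >= dominance ~ "worm",
        .data$f_nonworm >= dominance ~ "nonworm",
        TRUE ~ "ambiguous"
      )
    )
  list(detections = det, tracks = per_track)
}
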