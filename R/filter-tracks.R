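#' Crop a masked 80x80 ROI around a detection
#'
#' Extracts the classifier's input representation for one detection: an
#' 80x80 crop of the frame centred on the object centroid, with every pixel
#' further than `halo` from the object mask set to 0 (as in the masked
#' video).
#'
#' @param frame Numeric frame matrix (0..255).
#' @param det One-row detections tibble (from [segment_frame()]).
#' @param halo Mask halo in pixels.
#' @return Numeric 80x80 matrix.
#' @export
roi_from_detection <- function(frame, det, halo = 5) {
  H <- nrow(frame); W <- ncol(frame)
  px0 <- round(det$x) - 40L
  py0 <- round(det$y) - 40L
  m <- det$mask[[1]]
  mp <- which(m, arr.ind = TRUE)
  abs_y <- det$y_min + mp[, 1] - 1
  abs_x <- det$x_min + mp[, 2] - 1
  keep <- stamp_points_checked(abs_x, abs_y, disk_stencil(halo, H), H, W)
  r <- (keep - 1) %% H      # 0-based row (y)
  cc <- (keep - 1) %/% H    # 0-based col (x)
  sel <- r >= py0 & r < py0 + 80 & cc >= px0 & cc < px0 + 80
  roi <- matrix(0, 80, 80)
  roi[(r[sel] - py0 + 1) + (cc[sel] - px0) * 80] <- frame[keep[sel]]
  roi
}

#' Filter tracks with the worm/non-worm classifier
#'
#' For each track, one ROI per second of track duration is sampled (the
#' first detection of each whole second; tracks shorter than one second use
#' all frames), scored by the CNN, and the median worm probability taken.
#' A track is kept as a worm if and only if its median probability is
#' strictly greater than 0.5.
#'
#' @param classifier A `trained_classifier`.
#' @param tracks Tracks tibble (with `track_id`, `frame`, `t`, masks).
#' @param store The `frame_store` the tracks came from.
#' @param halo Mask halo in pixels.
#' @return Tracks tibble with `worm_probability_median` and `is_worm`
#'   columns.
#' @export
filter_tracks <- function(classifier, tracks, store, halo = 5) {
  if (!"t" %in% names(tracks)) {
    fps <- store$metadata$frame_rate
    tracks$t <- tracks$frame / fps
  }
  frames_cache <- new.env(parent = emptyenv())
  frame_of <- function(fn) {
    key <- as.character(fn)
    if (is.null(frames_cache[[key]])) {
      frames_cache[[key]] <- get_frame(store, fn)
    }
    frames_cache[[key]]
  }
  verdicts <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      t0 <- min(df$t)
      dur <- max(df$t) - t0
      rows <- if (dur < 1) {
        seq_len(nrow(df))
      } else {
        sec <- floor(df$t - t0)
        vapply(split(seq_len(nrow(df)), sec), `[`, 0L, 1)
      }
      rois <- array(0, dim = c(80, 80, length(rows)))
      for (k in seq_along(rows)) {
        i <- rows[k]
        rois[, , k] <- roi_from_detection(frame_of(df$frame[i]), df[i, ], halo)
      }
      tibble::tibble(
        worm_probability_median =
          stats::median(predict_worm_prob(classifier, rois)),
        n_scored = length(rows)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(is_worm = .data$worm_probability_median > 0.5)
  dplyr::left_join(tracks, verdicts, by = "track_id")
}

#' Median-probability verdict rule
#'
#' The filtering rule applied per track: median of the per-sample worm
#' probabilities, worm if and only if strictly greater than 0.5.
#'
#' @param probs Numeric vector of per-sample worm probabilities.
#' @return List with `median` and `is_worm`.
#' @export
median_probability_verdict <- function(probs) {
  m <- stats::median(probs)
  list(median = m, is_worm = m > 0.5)
}
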