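#' Segmentation parameters
#'
#' User-defined parameters of the contrast-based segmentation: putative worm
#' objects are connected components darker than `threshold` with pixel area
#' inside `[min_area, max_area]`.
#'
#' @param threshold Absolute grey level (0..255), or `"otsu"` to derive it
#'   from the image (computed over the well interiors when a grid is
#'   supplied, otherwise over the whole frame).
#' @param min_area,max_area Component area bounds in pixels.
#' @return A `segment_params` list.
#' @export
segment_params <- function(threshold = 100, min_area = 60, max_area = 3000) {
  structure(list(threshold = threshold, min_area = min_area,
                 max_area = max_area),
            class = "segment_params")
}

segment_threshold <- function(I, params, grid = NULL) {
  if (!identical(params$threshold, "otsu")) return(params$threshold)
  px <- if (!is.null(grid)) {
    wells <- if (inherits(grid, "well_grid")) grid$wells else grid
    sel <- rep(FALSE, length(I))
    H <- nrow(I)
    for (i in seq_len(nrow(wells))) {
      rows <- max(1, ceiling(wells$y_min[i] + 1)):min(H, floor(wells$y_max[i]))
      cols <- max(1, ceiling(wells$x_min[i] + 1)):min(ncol(I), floor(wells$x_max[i]))
      sel[as.vector(outer(rows, (cols - 1) * H, "+"))] <- TRUE
    }
    I[sel]
  } else {
    as.vector(I)
  }
  255 * EBImage::otsu(matrix(px / 255, ncol = 1), range = c(0, 1))
}

#' Segment putative worm objects in a frame
#'
#' Detects connected dark components within the configured area bounds and
#' extracts for each a centroid, bounding box, binary mask and midline (by
#' morphological thinning of the mask).
#'
#' @param frame 8-bit grayscale frame (raw or numeric matrix, 0..255).
#' @param params A [segment_params()].
#' @param frame_number Frame number recorded with each object.
#' @param grid Optional `well_grid` for Otsu thresholding over well
#'   interiors.
#' @return Tibble with one row per object: `frame`, `x`, `y` (centroid,
#'   0-based pixels), `area`, `x_min`/`y_min`/`x_max`/`y_max` (bounding
#'   box, half-open), `mask` (list of logical matrices), `midline` (list of
#'   k x 2 matrices, image coordinates), `length` (midline arc length, px).
#' @export
segment_frame <- function(frame, params = segment_params(),
                          frame_number = NA_integer_, grid = NULL) {
  I <- frame_to_num(frame)
  thr <- segment_threshold(I, params, grid)
  bin <- (I < thr) * 1
  lab <- EBImage::bwlabel(bin)
  n <- max(lab)
  empty <- tibble::tibble(
    frame = integer(), x = numeric(), y = numeric(), area = integer(),
    x_min = numeric(), y_min = numeric(), x_max = numeric(), y_max = numeric(),
    mask = list(), midline = list(), length = numeric()
  )
  if (n == 0) return(empty)
  H <- nrow(I)
  pix <- which(lab > 0)
  lab_of <- lab[pix]
  rows <- (pix - 1) %% H + 1
  cols <- (pix - 1) %/% H + 1
  out <- vector("list", n)
  for (k in seq_len(n)) {
    sel <- lab_of == k
    a <- sum(sel)
    if (a < params$min_area || a > params$max_area) next
    r <- rows[sel]; cc <- cols[sel]
    r0 <- min(r); r1 <- max(r); c0 <- min(cc); c1 <- max(cc)
    m <- matrix(FALSE, r1 - r0 + 1, c1 - c0 + 1)
    m[cbind(r - r0 + 1, cc - c0 + 1)] <- TRUE
    ml <- mask_midline(m, y0 = r0 - 1, x0 = c0 - 1)
    out[[k]] <- tibble::tibble(
      frame = as.integer(frame_number),
      x = mean(cc - 1), y = mean(r - 1), area = a,
      x_min = c0 - 1, y_min = r0 - 1, x_max = c1, y_max = r1,
      mask = list(m), midline = list(ml$path),
      length = ml$length
    )
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}

# Zhang-Suen thinning of a logical mask (vectorised over the image).
zs_thin <- function(mask) {
  m <- mask
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      pad[2:(H + 1), 2:(W + 1)] <- m
      P2 <- pad[1:H, 2:(W + 1)]       # N
      P3 <- pad[1:H, 3:(W + 2)]       # NE
      P4 <- pad[2:(H + 1), 3:(W + 2)] # E
      P5 <- pad[3:(H + 2), 3:(W + 2)] # SE
      P6 <- pad[3:(H + 2), 2:(W + 1)] # S
      P7 <- pad[3:(H + 2), 1:W]       # SW
      P8 <- pad[2:(H + 1), 1:W]       # W
      P9 <- pad[1:H, 1:W]             # NW
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
        (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      if (sub == 1) {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Ordered midline of a mask: thin to a skeleton, then take the longest
# geodesic path through it. Coordinates returned 0-based (x, y) in image
# space given the mask's offset.
mask_midline <- function(mask, y0 = 0, x0 = 0) {
  sk <- zs_thin(mask)
  pts <- which(sk, arr.ind = TRUE)
  if (nrow(pts) == 0) {
    pts <- which(mask, arr.ind = TRUE)
    cen <- colMeans(pts)
    path <- cbind(x = x0 + cen[2] - 1, y = y0 + cen[1] - 1)
    return(list(path = path, length = 0))
  }
  # longest geodesic path via double BFS on the padded skeleton raster
  H <- nrow(sk); W <- ncol(sk)
  Hp <- H + 2L
  P <- matrix(FALSE, Hp, W + 2L)
  P[2:(H + 1), 2:(W + 1)] <- sk
  offs <- c(-1L, 1L, -Hp, Hp, -Hp - 1L, -Hp + 1L, Hp - 1L, Hp + 1L)
  n_sk <- sum(P)
  bfs_far <- function(start) {
    prev <- integer(length(P))
    seen <- logical(length(P))
    seen[start] <- TRUE
    queue <- integer(n_sk)
    queue[1] <- start
    head <- 1L; tail <- 1L; last <- start
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L; last <- cur
      nbs <- cur + offs
      nbs <- nbs[P[nbs] & !seen[nbs]]
      if (length(nbs)) {
        seen[nbs] <- TRUE
        prev[nbs] <- cur
        queue[(tail + 1L):(tail + length(nbs))] <- nbs
        tail <- tail + length(nbs)
      }
    }
    list(far = last, prev = prev)
  }
  start <- which(P)[1]
  a <- bfs_far(start)$far
  b <- bfs_far(a)
  path_idx <- b$far
  while (b$prev[path_idx[1]] != 0L) {
    path_idx <- c(b$prev[path_idx[1]], path_idx)
  }
  pr <- (path_idx - 1L) %% Hp       # padded 0-based row
  pc <- (path_idx - 1L) %/% Hp      # padded 0-based col
  path <- cbind(
    x = x0 + pc - 1,
    y = y0 + pr - 1
  )
  len <- if (nrow(path) > 1) {
    sum(sqrt(rowSums(diff(path)^2)))
  } else 0
  list(path = path, length = len)
}

#' Mask a frame around its putative objects
#'
#' Sets every pixel whose euclidean distance to the nearest object pixel
#' exceeds `halo` to exactly 0, leaving the rest unchanged: the "masked
#' video" representation that is stored and later cropped into ROI images.
#' Idempotent for fixed objects.
#'
#' @param frame 8-bit grayscale frame (raw or numeric, 0..255).
#' @param objects Output of [segment_frame()] for this frame.
#' @param halo Distance threshold in pixels.
#' @return Numeric matrix of the same size.
#' @export
mask_frame <- function(frame, objects, halo = 5) {
  I <- frame_to_num(frame)
  if (nrow(objects) == 0) return(I * 0)
  obj <- matrix(0, nrow(I), ncol(I))
  for (i in seq_len(nrow(objects))) {
    m <- objects$mask[[i]]
    rr <- objects$y_min[i] + seq_len(nrow(m))
    cc <- objects$x_min[i] + seq_len(ncol(m))
    obj[rr, cc] <- pmax(obj[rr, cc], m * 1)
  }
  d <- EBImage::distmap(1 - obj)
  I[d > halo] <- 0
  I
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour assignment between consecutive frames: pairs
#' closer than `max_step` are linked in order of increasing distance;
#' unmatched detections start new tracks; a track that misses a frame is
#' closed (a later reappearance starts a new track), so tracks never
#' merge and the number of tracks is typically larger than the number of
#' worms.
#'
#' @param detections Row-bound [segment_frame()] outputs with a valid
#'   `frame` column.
#' @param max_step Maximum centroid displacement per frame, pixels.
#' @return The detections tibble with a `track_id` column, ordered by
#'   track and frame.
#' @export
link_tracks <- function(detections, max_step = 12) {
  if (nrow(detections) == 0) {
    return(dplyr::mutate(detections, track_id = integer()))
  }
  det <- dplyr::arrange(detections, .data$frame)
  det$track_id <- NA_integer_
  frames <- sort(unique(det$frame))
  next_id <- 1L
  prev_rows <- integer(0)
  prev_frame <- NA_integer_
  for (f in frames) {
    cur_rows <- which(det$frame == f)
    # a missed frame closes the track: matching only spans consecutive frames
    if (!is.na(prev_frame) && f != prev_frame + 1L) prev_rows <- integer(0)
    if (length(prev_rows) && length(cur_rows)) {
      dmat <- outer(det$x[prev_rows], det$x[cur_rows], "-")^2 +
        outer(det$y[prev_rows], det$y[cur_rows], "-")^2
      ord <- order(dmat)
      used_p <- logical(length(prev_rows))
      used_c <- logical(length(cur_rows))
      for (k in ord) {
        if (dmat[k] > max_step^2) break
        i <- (k - 1) %% length(prev_rows) + 1
        j <- (k - 1) %/% length(prev_rows) + 1
        if (used_p[i] || used_c[j]) next
        det$track_id[cur_rows[j]] <- det$track_id[prev_rows[i]]
        used_p[i] <- TRUE; used_c[j] <- TRUE
      }
    }
    new_rows <- cur_rows[is.na(det$track_id[cur_rows])]
    if (length(new_rows)) {
      det$track_id[new_rows] <- next_id + seq_along(new_rows) - 1L
      next_id <- next_id + length(new_rows)
    }
    prev_rows <- cur_rows
    prev_frame <- f
  }
  dplyr::arrange(det, .data$track_id, .data$frame)
}

# orientation-align the midlines of one track and set head-first order by
# the majority-direction-of-motion rule (head leads while moving forward)
orient_track_midlines <- function(mls, xs, ys) {
  n <- length(mls)
  if (n == 0) return(mls)
  for (k in seq_len(n)[-1]) {
    a <- mls[[k]]; prev <- mls[[k - 1]]
    if (nrow(a) < 2 || nrow(prev) < 2) next
    d_same <- sum((a[1, ] - prev[1, ])^2) + sum((a[nrow(a), ] - prev[nrow(prev), ])^2)
    d_flip <- sum((a[1, ] - prev[nrow(prev), ])^2) + sum((a[nrow(a), ] - prev[1, ])^2)
    if (d_flip < d_same) mls[[k]] <- a[rev(seq_len(nrow(a))), , drop = FALSE]
  }
  # majority rule: net displacement should project positively on the
  # tail -> head axis
  proj <- 0
  for (k in seq_len(n)[-1]) {
    a <- mls[[k]]
    if (nrow(a) < 2) next
    axis <- a[1, ] - a[nrow(a), ]
    nv <- sqrt(sum(axis^2))
    if (nv == 0) next
    proj <- proj + sum(c(xs[k] - xs[k - 1], ys[k] - ys[k - 1]) * axis / nv)
  }
  if (proj < 0) {
    mls <- lapply(mls, function(a) a[rev(seq_len(nrow(a))), , drop = FALSE])
  }
  mls
}

#' Resolve head/tail orientation for every track
#'
#' Aligns midline orientation across the frames of each track (minimal
#' end-to-end displacement) and then orients each track head-first using
#' the majority direction of motion: over the whole track the head leads
#' during forward crawling. Ties leave the orientation unchanged (stable).
#'
#' @param tracks Output of [link_tracks()].
#' @return The tracks tibble with consistently oriented `midline`s.
#' @export
resolve_head_tail <- function(tracks) {
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      df$midline <- orient_track_midlines(df$midline, df$x, df$y)
      df
    }) |>
    dplyr::ungroup()
}

# central-difference gradient, one-sided at the ends
num_gradient <- function(x) {
  n <- length(x)
  if (n == 1) return(0)
  g <- numeric(n)
  g[1] <- x[2] - x[1]
  g[n] <- x[n] - x[n - 1]
  if (n > 2) g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  g
}

rollmean_center <- function(x, w) {
  n <- length(x)
  if (n == 0 || w <= 1) return(x)
  h <- (w - 1) %/% 2
  cs <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  cnt <- cumsum(c(0, !is.na(x)))
  lo <- pmax(0, seq_len(n) - h - 1)
  hi <- pmin(n, seq_len(n) + h)
  s <- cs[hi + 1] - cs[lo + 1]
  k <- cnt[hi + 1] - cnt[lo + 1]
  out <- s / k
  out[k == 0] <- NA_real_
  out
}

#' Classify per-frame motion modes
#'
#' Signed crawling speed is the centroid velocity projected on the
#' tail-to-head midline axis, smoothed with a centred moving average.
#' Frames with |speed| below `v_stat` body lengths per second are
#' stationary; otherwise the sign gives forward or backward. Midline
#' orientation is taken as stored (run [resolve_head_tail()] first); given
#' fixed midlines the classification is antisymmetric under time reversal.
#'
#' @param tracks Tracks tibble (from [resolve_head_tail()]).
#' @param frame_rate Frames per second.
#' @param v_stat Stationary threshold, in body lengths per second.
#' @param smooth_window Smoothing window in seconds.
#' @return Tracks tibble with a `mode` factor column (`fw`/`bw`/`st`,
#'   `NA` where the midline is missing).
#' @export
classify_motion <- function(tracks, frame_rate, v_stat = 0.1,
                            smooth_window = 0.4) {
  w <- max(1, round(smooth_window * frame_rate))
  if (w %% 2 == 0) w <- w + 1
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      body_len <- stats::median(df$length[df$length > 0])
      if (!is.finite(body_len) || body_len <= 0) body_len <- 1
      # central differences: antisymmetric under time reversal
      vx <- num_gradient(df$x) * frame_rate
      vy <- num_gradient(df$y) * frame_rate
      sp <- rep(NA_real_, n)
      ok <- rep(FALSE, n)
      for (k in seq_len(n)) {
        ml <- df$midline[[k]]
        if (is.null(ml) || nrow(ml) < 2) next
        axis <- ml[1, ] - ml[nrow(ml), ]
        nv <- sqrt(sum(axis^2))
        if (nv == 0) next
        ok[k] <- TRUE
        sp[k] <- (vx[k] * axis[1] + vy[k] * axis[2]) / nv
      }
      sps <- rollmean_center(sp, w)
      thr <- v_stat * body_len
      mode <- ifelse(abs(sps) < thr, "st", ifelse(sps > 0, "fw", "bw"))
      mode[!ok] <- NA_character_
      df$signed_speed <- sps
      df$body_length <- body_len
      df$mode <- factor(mode, levels = MOTION_MODES)
      df
    }) |>
    dplyr::ungroup()
}

#' Assign tracks to wells
#'
#' Each track is assigned to the well containing its median centroid;
#' tracks whose median lies on a wall band (or outside the lattice) are
#' discarded, with the count recorded in the `discarded_tracks` attribute.
#' Bad-well flags propagate to the tracks.
#'
#' @param tracks Tracks tibble.
#' @param grid A `well_grid` (or truth wells tibble).
#' @return Tracks tibble with `well` and `bad` columns; discarded-track
#'   count in `attr(, "discarded_tracks")`.
#' @export
assign_tracks <- function(tracks, grid) {
  med <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(mx = stats::median(.data$x),
                     my = stats::median(.data$y))
  med$well <- locate_point(grid, med$mx, med$my)
  wells <- if (inherits(grid, "well_grid")) grid$wells else grid
  med$bad <- wells$bad[match(med$well, wells$name)]
  dropped <- sum(is.na(med$well))
  out <- tracks |>
    dplyr::inner_join(
      med[!is.na(med$well), c("track_id", "well", "bad")],
      by = "track_id"
    )
  attr(out, "discarded_tracks") <- dropped
  out
}

#' Run the full per-session tracking pipeline
#'
#' Segment every frame, link detections into tracks, orient midlines,
#' classify motion modes and assign tracks to the wells of a fitted grid.
#'
#' @param store A `frame_store` with frames.
#' @param grid A `well_grid` (or truth wells tibble).
#' @param params A [segment_params()].
#' @param max_step Linking threshold in pixels/frame.
#' @param v_stat,smooth_window See [classify_motion()].
#' @return Tracks tibble.
#' @export
track_session <- function(store, grid, params = segment_params(),
                          max_step = 12, v_stat = 0.1, smooth_window = 0.4) {
  dets <- purrr::map2_dfr(
    store$frames, store$index$frame_number,
    function(fr, fn) segment_frame(fr, params, frame_number = fn, grid = grid)
  )
  fps <- store$metadata$frame_rate
  dets |>
    link_tracks(max_step = max_step) |>
    resolve_head_tail() |>
    classify_motion(frame_rate = fps, v_stat = v_stat,
                    smooth_window = smooth_window) |>
    dplyr::mutate(t = .data$frame / fps) |>
    assign_tracks(grid)
}
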