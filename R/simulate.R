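#' Simulate worm motion-mode chains (no rendering)
#'
#' Runs the per-frame three-state Markov chain for every worm of a virtual
#' plate under a stimulus schedule, without rendering frames. During
#' light-on intervals, transitions into the forward mode are multiplied by
#' `light_bias` and rows renormalised. This is the fast path for
#' photoresponse statistics, where only per-worm mode series matter.
#'
#' @param n_wells Number of wells to simulate.
#' @param worms A [worm_kinematics()].
#' @param schedule A [build_schedule()] schedule.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param frame_rate Frames per second; defaults to `worms$frame_rate`. The
#'   transition matrix is interpreted per frame.
#' @param light_bias_by_pulse Optional numeric vector, one multiplier per
#'   pulse of the schedule, overriding `worms$light_bias` pulse by pulse
#'   (used to simulate sensitisation).
#' @return Tibble with `well`, `worm_id`, `frame`, `t`, `mode`.
#' @export
simulate_mode_tracks <- function(n_wells, worms = worm_kinematics(),
                                 schedule = build_schedule("standard"),
                                 seed = 0, frame_rate = NULL,
                                 light_bias_by_pulse = NULL) {
  set.seed(seed)
  fps <- frame_rate %||% worms$frame_rate
  n_frames <- round(schedule$total_duration * fps)
  nw <- n_wells * worms$n_worms_per_well
  tt <- (seq_len(n_frames) - 1) / fps
  M <- simulate_modes(nw, tt, worms, schedule, light_bias_by_pulse)
  wells <- sprintf("W%02d", rep(seq_len(n_wells), each = worms$n_worms_per_well))
  tibble::tibble(
    well = rep(wells, each = n_frames),
    worm_id = rep(seq_len(nw), each = n_frames),
    frame = rep(seq_len(n_frames) - 1L, nw),
    t = rep(tt, nw),
    mode = factor(MOTION_MODES[as.vector(t(M))], levels = MOTION_MODES)
  )
}

# Mode chains for `nw` worms over timestamps `tt`; returns nw x n_frames
# integer matrix of mode indices into MOTION_MODES. Uses the current RNG
# stream.
simulate_modes <- function(nw, tt, worms, schedule, light_bias_by_pulse = NULL) {
  n_frames <- length(tt)
  P0 <- worms$mode_transition_matrix
  lit <- light_on(schedule, tt)
  pulse_of <- rep(NA_integer_, n_frames)
  if (!is.null(light_bias_by_pulse)) {
    for (i in seq_len(nrow(schedule$pulses))) {
      sel <- tt >= schedule$pulses$t_start[i] & tt < schedule$pulses$t_end[i]
      pulse_of[sel] <- i
    }
    biases <- unique(light_bias_by_pulse)
    P1s <- lapply(biases, function(b) bias_mode_matrix(P0, b))
    names(P1s) <- as.character(biases)
  } else {
    P1 <- bias_mode_matrix(P0, worms$light_bias)
  }
  M <- matrix(NA_integer_, nrow = nw, ncol = n_frames)
  pi0 <- stationary_distribution(P0)
  M[, 1] <- sample.int(3L, nw, replace = TRUE, prob = pi0)
  for (k in seq_len(n_frames - 1L)) {
    P <- if (!lit[k + 1]) {
      P0
    } else if (is.null(light_bias_by_pulse)) {
      P1
    } else {
      P1s[[as.character(light_bias_by_pulse[pulse_of[k + 1]])]]
    }
    pr <- P[M[, k], , drop = FALSE]
    r <- stats::runif(nw)
    M[, k + 1] <- 1L + (r > pr[, 1]) + (r > pr[, 1] + pr[, 2])
  }
  M
}

# Arc-length elongation factor of the sinusoidal midline, so that the chord
# parameterisation yields the requested body length.
undulation_elongation <- function(amplitude, wavelength) {
  k <- 2 * pi * amplitude / wavelength
  u <- seq(0, 2 * pi, length.out = 513)
  mean(sqrt(1 + (k * cos(u))^2))
}

# Midline sample points for one worm. Returns n_pts x 2 matrix (x, y),
# head first.
worm_midline <- function(cx, cy, theta, phase, worms, n_pts = 41) {
  elong <- undulation_elongation(worms$undulation_amplitude,
                                 worms$undulation_wavelength)
  Lc <- worms$body_length / elong
  s <- seq(-Lc / 2, Lc / 2, length.out = n_pts)
  ux <- cos(theta); uy <- sin(theta)
  off <- worms$undulation_amplitude *
    sin(2 * pi * s * elong / worms$undulation_wavelength + phase)
  pts <- cbind(
    cx + s * ux - off * uy,
    cy + s * uy + off * ux
  )
  pts[rev(seq_len(n_pts)), , drop = FALSE] # head (s = +L/2) first
}

# Disk stencil of linear-index offsets for an H-row image.
disk_stencil <- function(radius, H) {
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[g$dy^2 + g$dx^2 <= radius^2, ]
  list(lin = g$dy + g$dx * H, dy = g$dy, dx = g$dx)
}

# Linear indices (1-based, column-major) of disks of `radius` stamped at
# 0-based pixel coordinates (px, py). Assumes the disks lie inside the image.
stamp_points <- function(px, py, stencil, H) {
  base <- (round(py) + 1) + round(px) * H
  unique(rep(base, each = length(stencil$lin)) +
           rep(stencil$lin, times = length(base)))
}

# As stamp_points, but drops stencil pixels falling outside an H x W image.
stamp_points_checked <- function(px, py, stencil, H, W) {
  py <- round(py); px <- round(px)
  yy <- rep(py, each = length(stencil$dy)) + rep(stencil$dy, times = length(py))
  xx <- rep(px, each = length(stencil$dx)) + rep(stencil$dx, times = length(px))
  ok <- yy >= 0 & yy < H & xx >= 0 & xx < W
  unique((yy[ok] + 1) + xx[ok] * H)
}

# Random static debris in a well: pixel index set + intensity value.
make_debris <- function(box, H, W, worms, type = NULL) {
  type <- type %||% sample(c("blob", "scratch", "crescent"), 1)
  pad <- 12
  cx <- stats::runif(1, box$x_min + pad, box$x_max - pad)
  cy <- stats::runif(1, box$y_min + pad, box$y_max - pad)
  if (type == "blob") {
    rx <- stats::runif(1, 4, 8); ry <- stats::runif(1, 4, 8)
    a <- stats::runif(1, 0, pi)
    g <- expand.grid(dy = -10:10, dx = -10:10)
    xr <- g$dx * cos(a) + g$dy * sin(a)
    yr <- -g$dx * sin(a) + g$dy * cos(a)
    keep <- (xr / rx)^2 + (yr / ry)^2 <= 1
    px <- round(cx) + g$dx[keep]; py <- round(cy) + g$dy[keep]
    ok <- px >= 0 & px < W & py >= 0 & py < H
    px <- px[ok]; py <- py[ok]
    lin <- unique((py + 1) + px * H)
  } else if (type == "scratch") {
    len <- stats::runif(1, 20, 40); a <- stats::runif(1, 0, pi)
    s <- seq(-len / 2, len / 2, by = 0.7)
    px <- cx + s * cos(a); py <- cy + s * sin(a)
    lin <- stamp_points_checked(px, py, disk_stencil(1.2, H), H, W)
  } else {
    rad <- stats::runif(1, 12, 20); a0 <- stats::runif(1, 0, 2 * pi)
    a <- seq(a0, a0 + 2 * pi / 3, length.out = 60)
    px <- cx + rad * cos(a); py <- cy + rad * sin(a)
    lin <- stamp_points_checked(px, py, disk_stencil(1.5, H), H, W)
  }
  # contrast kept below the default segmentation threshold so debris is
  # actually detected and tracked (and must be rejected by the classifier)
  value <- stats::runif(1, 0.20, 0.36)
  list(type = type, x = mean(px), y = mean(py), lin = lin, value = value)
}

#' Simulate a full imaging session of a multiwell plate
#'
#' Renders brightfield-like frames of square wells containing worms that move
#' according to a three-state (forward/backward/stationary) Markov chain
#' modulated by a blue-light stimulus schedule, and returns the frames
#' together with complete ground truth (per-worm per-frame position, midline,
#' motion mode, and well assignment).
#'
#' Worms are dark sinusoidal tubes on the bright well interior; their
#' midline undulation advances with crawling, forwards motion is towards the
#' head, and each worm is confined to its well's inner square. Optional
#' static debris objects (dark blobs, scratches, and arc-shaped crescents)
#' can be added to exercise the non-worm filtering stages.
#'
#' @param plate A [plate_config()].
#' @param worms A [worm_kinematics()].
#' @param schedule A [build_schedule()] schedule; frames are rendered at
#'   `worms$frame_rate` for its full duration.
#' @param seed Integer seed; identical seeds give byte-identical stores.
#' @param render If `FALSE`, skip frame rendering (ground truth only).
#' @param n_debris Number of static debris objects scattered across wells.
#' @param noise_sd Per-pixel gaussian noise, as a fraction of the intensity
#'   range (0 disables noise).
#' @param row_offset,col_offset Lattice offsets in pixels (default
#'   `plate$margin`).
#' @param camera_id Optional camera index (1..6) for plate-level well names.
#' @return A `worm_session`: list with `store` (a `frame_store`: `frames`
#'   list of raw 8-bit matrices, `index` tibble of `frame_number` /
#'   `timestamp_s`, `metadata`), `truth` (tibble with one row per object per
#'   frame: `object_id`, `label`, `well`, `frame`, `t`, `x`, `y`, `mode`,
#'   `midline` list-column), and `wells` (truth well boxes).
#' @export
simulate_session <- function(plate = plate_config(),
                             worms = worm_kinematics(),
                             schedule, seed = 0,
                             render = TRUE, n_debris = 0, noise_sd = 0,
                             row_offset = NULL, col_offset = NULL,
                             camera_id = NULL) {
  set.seed(seed)
  row_offset <- row_offset %||% plate$margin
  col_offset <- col_offset %||% plate$margin
  wells <- well_boxes(plate, row_offset, col_offset, camera_id)
  fps <- worms$frame_rate
  n_frames <- round(schedule$total_duration * fps)
  stopifnot(n_frames >= 1)
  H <- plate$image_size[1]; W <- plate$image_size[2]

  elong <- undulation_elongation(worms$undulation_amplitude,
                                 worms$undulation_wavelength)
  half_extent <- worms$body_length / elong / 2 +
    worms$undulation_amplitude + worms$body_width / 2 + 1
  if (2 * half_extent >= plate$well_size) {
    stop("worms of this body length cannot fit inside a well", call. = FALSE)
  }
  # the worm *centre* is confined to this inset of the inner square; the
  # body may transiently overhang the wall band, as real worms do
  conf_margin <- worms$undulation_amplitude + worms$body_width / 2 + 2
  worm_area <- worms$body_length * worms$body_width
  if (worms$n_worms_per_well * worm_area > 0.5 * plate$well_size^2) {
    stop("too many worms per well for this body length", call. = FALSE)
  }

  n_wells <- nrow(wells)
  nw <- n_wells * worms$n_worms_per_well
  worm_well <- rep(seq_len(n_wells), each = worms$n_worms_per_well)

  # initial worm state: centres spread out within each well to avoid
  # overlapping bodies at t = 0
  cx <- numeric(nw); cy <- numeric(nw)
  x_lo0 <- wells$x_min[worm_well] + conf_margin
  x_hi0 <- wells$x_max[worm_well] - conf_margin
  y_lo0 <- wells$y_min[worm_well] + conf_margin
  y_hi0 <- wells$y_max[worm_well] - conf_margin
  min_sep <- min(0.4 * plate$well_size, worms$body_length / 2)
  for (w in seq_len(n_wells)) {
    ids <- which(worm_well == w)
    for (attempt in 1:200) {
      px <- stats::runif(length(ids), x_lo0[ids], x_hi0[ids])
      py <- stats::runif(length(ids), y_lo0[ids], y_hi0[ids])
      if (length(ids) < 2 ||
          min(stats::dist(cbind(px, py))) >= min_sep) break
    }
    cx[ids] <- px; cy[ids] <- py
  }
  theta <- stats::runif(nw, 0, 2 * pi)
  phase <- stats::runif(nw, 0, 2 * pi)

  tt <- (seq_len(n_frames) - 1) / fps
  M <- simulate_modes(nw, tt, worms, schedule)

  debris <- list()
  if (n_debris > 0) {
    dwells <- sample.int(n_wells, n_debris, replace = TRUE)
    debris <- lapply(seq_len(n_debris), function(i) {
      d <- make_debris(wells[dwells[i], ], H, W, worms)
      d$well <- wells$name[dwells[i]]
      d
    })
  }

  dt <- 1 / fps
  speeds <- c(fw = worms$speed_fw, bw = -worms$speed_bw, st = 0)
  wave_speed <- 2 * pi * worms$speed_fw / worms$undulation_wavelength

  bg <- round(255 * render_background(plate, row_offset, col_offset))
  bg_vec <- as.vector(bg)
  stencil <- disk_stencil(worms$body_width / 2, H)
  worm_val <- round(255 * worms$worm_contrast)

  frames <- if (render) vector("list", n_frames) else NULL
  Xs <- matrix(NA_real_, nw, n_frames)
  Ys <- matrix(NA_real_, nw, n_frames)
  midlines <- vector("list", nw * n_frames)

  x_lo <- wells$x_min[worm_well] + conf_margin
  x_hi <- wells$x_max[worm_well] - conf_margin
  y_lo <- wells$y_min[worm_well] + conf_margin
  y_hi <- wells$y_max[worm_well] - conf_margin
  wx_c <- (x_lo + x_hi) / 2
  wy_c <- (y_lo + y_hi) / 2
  steer_zone <- 25

  for (k in seq_len(n_frames)) {
    if (k > 1) {
      v <- speeds[M[, k]]
      moving <- v != 0
      theta <- theta + stats::rnorm(nw, 0, 0.12) * ifelse(moving, 1, 0.2)
      # steer moving worms smoothly back towards the well centre when they
      # approach the boundary (no instantaneous body flips)
      d_bound <- pmin(cx - x_lo, x_hi - cx, cy - y_lo, y_hi - cy)
      near <- moving & d_bound < steer_zone
      if (any(near)) {
        theta_eff <- theta + ifelse(v < 0, pi, 0)
        phi <- atan2(wy_c - cy, wx_c - cx)
        dang <- atan2(sin(phi - theta_eff), cos(phi - theta_eff))
        gain <- 0.25 * (1 - pmax(0, d_bound) / steer_zone)
        turn <- sign(dang) * pmin(abs(dang), gain)
        theta[near] <- theta[near] + turn[near]
      }
      cx <- cx + v * dt * cos(theta)
      cy <- cy + v * dt * sin(theta)
      phase <- phase + sign(v) * wave_speed * dt
      cx <- pmin(pmax(cx, x_lo), x_hi)
      cy <- pmin(pmax(cy, y_lo), y_hi)
    }
    if (render) vals <- bg_vec
    for (i in seq_len(nw)) {
      ml <- worm_midline(cx[i], cy[i], theta[i], phase[i], worms)
      midlines[[(i - 1) * n_frames + k]] <- ml
      cen <- colMeans(ml)
      Xs[i, k] <- cen[1]; Ys[i, k] <- cen[2]
      if (render) {
        lin <- stamp_points_checked(ml[, 1], ml[, 2], stencil, H, W)
        vals[lin] <- worm_val
      }
    }
    if (render) {
      for (d in debris) vals[d$lin] <- round(255 * d$value)
      if (noise_sd > 0) {
        vals <- vals + stats::rnorm(length(vals), 0, noise_sd * 255)
      }
      fr <- as.raw(pmin(255, pmax(0, round(vals))))
      dim(fr) <- c(H, W)
      frames[[k]] <- fr
    }
  }

  worm_truth <- tibble::tibble(
    object_id = rep(seq_len(nw), each = n_frames),
    label = "worm",
    well = rep(wells$name[worm_well], each = n_frames),
    frame = rep(seq_len(n_frames) - 1L, nw),
    t = rep(tt, nw),
    x = as.vector(t(Xs)),
    y = as.vector(t(Ys)),
    mode = factor(MOTION_MODES[as.vector(t(M))], levels = MOTION_MODES),
    midline = midlines
  )
  truth <- worm_truth
  if (n_debris > 0) {
    deb_truth <- tibble::tibble(
      object_id = rep(nw + seq_len(n_debris), each = n_frames),
      label = "nonworm",
      well = rep(vapply(debris, `[[`, "", "well"), each = n_frames),
      frame = rep(seq_len(n_frames) - 1L, n_debris),
      t = rep(tt, n_debris),
      x = rep(vapply(debris, `[[`, 0, "x"), each = n_frames),
      y = rep(vapply(debris, `[[`, 0, "y"), each = n_frames),
      mode = factor(NA_character_, levels = MOTION_MODES),
      midline = rep(list(NULL), n_debris * n_frames)
    )
    truth <- dplyr::bind_rows(worm_truth, deb_truth)
  }

  store <- structure(
    list(
      frames = frames,
      index = tibble::tibble(frame_number = seq_len(n_frames) - 1L,
                             timestamp_s = tt),
      metadata = list(
        frame_rate = fps,
        px_per_mm = plate$px_per_mm,
        camera_id = camera_id %||% 1L,
        image_size = plate$image_size,
        schedule = list(
          segments = as.data.frame(schedule$segments),
          total_duration = schedule$total_duration
        )
      )
    ),
    class = "frame_store"
  )
  structure(
    list(store = store, truth = truth, wells = wells,
         plate = plate, worms = worms, schedule = schedule,
         row_offset = row_offset, col_offset = col_offset),
    class = "worm_session"
  )
}

#' @exportS3Method base::print
print.frame_store <- function(x, ...) {
  cat(sprintf(
    "<frame_store> %d frame(s) @ %g fps%s\n",
    nrow(x$index), x$metadata$frame_rate,
    if (is.null(x$frames)) " (index only)" else ""
  ))
  invisible(x)
}

#' Render a single synthetic plate frame
#'
#' One frame of a plate with optional worms and noise, plus the ground-truth
#' well boxes. Convenience wrapper used for well-detection studies.
#'
#' @inheritParams simulate_session
#' @param with_worms Render worms (`TRUE`) or just the empty plate.
#' @return List with `frame` (numeric matrix, 0..255), `wells` (truth
#'   boxes), `row_offset`, `col_offset`.
#' @export
render_plate_frame <- function(plate = plate_config(),
                               worms = worm_kinematics(),
                               seed = 0, noise_sd = 0,
                               row_offset = NULL, col_offset = NULL,
                               with_worms = TRUE) {
  sched <- build_schedule("custom",
                          segments = data.frame(label = "off",
                                                duration = 1 / worms$frame_rate))
  ses <- simulate_session(
    plate,
    if (with_worms) worms else modifyList_worms(worms, n_worms_per_well = 0L),
    sched,
    seed = seed, render = TRUE, noise_sd = noise_sd,
    row_offset = row_offset, col_offset = col_offset
  )
  list(
    frame = frame_to_num(ses$store$frames[[1]]),
    wells = ses$wells,
    row_offset = ses$row_offset, col_offset = ses$col_offset
  )
}

# tweak a worm_kinematics without re-validating a zero worm count
modifyList_worms <- function(worms, ...) {
  w <- unclass(worms)
  w[names(list(...))] <- list(...)
  class(w) <- "worm_kinematics"
  w
}
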