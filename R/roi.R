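#' Generate a labelled worm / non-worm ROI image set
#'
#' Produces balanced 80x80 8-bit grayscale "masked" region-of-interest
#' images of the kind the tracking pipeline crops around putative objects:
#' a dark object on the bright well background, with every pixel further
#' than a halo from the object set to exactly 0 (mimicking video masking).
#' The worm class is a curved sinusoidal filament; the non-worm class is
#' debris (gaussian-ish blobs, straight scratches, arc crescents).
#'
#' @param n_per_class Images per class (>= 1).
#' @param seed Integer seed.
#' @param halo Mask halo in pixels around the object.
#' @param noise_sd Background/object gaussian noise, in grey levels.
#' @return List with `images` (integer array `80 x 80 x 2*n_per_class`,
#'   values 0..255) and `labels` (factor, levels `c("worm", "nonworm")`).
#' @export
make_roi_dataset <- function(n_per_class, seed = 0, halo = 5, noise_sd = 3) {
  stopifnot(n_per_class >= 1)
  set.seed(seed)
  n <- 2L * n_per_class
  images <- array(0L, dim = c(80, 80, n))
  labels <- factor(rep(c("worm", "nonworm"), times = n_per_class),
                   levels = c("worm", "nonworm"))
  for (i in seq_len(n)) {
    images[, , i] <- render_roi(as.character(labels[i]), halo, noise_sd)
  }
  list(images = images, labels = labels)
}

# one 80x80 masked ROI
render_roi <- function(label, halo = 5, noise_sd = 3) {
  H <- 80L
  bg <- 255
  obj_contrast <- stats::runif(1, 0.20, 0.38)
  cx <- stats::runif(1, 32, 48); cy <- stats::runif(1, 32, 48)
  if (label == "worm") {
    wk <- worm_kinematics(
      body_length = stats::runif(1, 50, 75),
      body_width = stats::runif(1, 4, 7),
      undulation_amplitude = stats::runif(1, 3, 8),
      undulation_wavelength = stats::runif(1, 40, 70),
      worm_contrast = obj_contrast
    )
    ml <- worm_midline(cx, cy, stats::runif(1, 0, 2 * pi),
                       stats::runif(1, 0, 2 * pi), wk)
    # a share of worm ROIs contain two touching/crossing worms, as crops of
    # real multi-worm wells do
    if (stats::runif(1) < 0.3) {
      ml2 <- worm_midline(cx + stats::runif(1, -10, 10),
                          cy + stats::runif(1, -10, 10),
                          stats::runif(1, 0, 2 * pi),
                          stats::runif(1, 0, 2 * pi), wk)
      ml <- rbind(ml, ml2)
    }
    ml[, 1] <- pmin(pmax(ml[, 1], 3), H - 4)
    ml[, 2] <- pmin(pmax(ml[, 2], 3), H - 4)
    lin <- stamp_points_checked(ml[, 1], ml[, 2],
                                disk_stencil(wk$body_width / 2, H), H, H)
    keep <- stamp_points_checked(ml[, 1], ml[, 2],
                                 disk_stencil(wk$body_width / 2 + halo, H), H, H)
  } else {
    box <- list(x_min = 18, x_max = 62, y_min = 18, y_max = 62)
    d <- make_debris(box, H, H, NULL)
    pts <- cbind((d$lin - 1) %/% H, (d$lin - 1) %% H) # (x, y), 0-based
    # centre the object's pixel centroid in the crop, as detection crops are
    pts[, 1] <- pts[, 1] + round(40 - mean(pts[, 1]))
    pts[, 2] <- pts[, 2] + round(40 - mean(pts[, 2]))
    ok <- pts[, 1] >= 0 & pts[, 1] < H & pts[, 2] >= 0 & pts[, 2] < H
    pts <- pts[ok, , drop = FALSE]
    lin <- (pts[, 2] + 1) + pts[, 1] * H
    keep <- stamp_points_checked(pts[, 1], pts[, 2], disk_stencil(halo, H), H, H)
    obj_contrast <- d$value
  }
  img <- matrix(bg + stats::rnorm(H * H, 0, noise_sd), H, H)
  # crops near well edges include part of the darker wall/shadow band
  if (stats::runif(1) < 0.4) {
    w <- round(stats::runif(1, 5, 30))
    side <- sample(4, 1)
    sel <- switch(side,
      seq_len(w), H - seq_len(w) + 1, seq_len(w), H - seq_len(w) + 1)
    dark <- stats::runif(1, 0.4, 0.6)
    if (side <= 2) img[sel, ] <- img[sel, ] * dark else
      img[, sel] <- img[, sel] * dark
  }
  img[lin] <- 255 * obj_contrast + stats::rnorm(length(lin), 0, noise_sd)
  out <- matrix(0, H, H)
  out[keep] <- img[keep]
  m <- matrix(as.integer(pmin(255, pmax(0, round(out)))), H, H)
  # masked background must be exactly 0; object pixels must not be
  m[m == 0 & seq_along(m) %in% keep] <- 1L
  m
}
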