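#' Plate geometry configuration
#'
#' Describes the square-well plate geometry seen by a single camera of the
#' array. The default is the 4x4 block of a 96-well square-well plate that one
#' camera images: wells on a regular lattice, bright flat-bottomed interiors
#' separated by darker wall/shadow bands. Coordinates are 0-based pixel
#' indices, origin at the top-left corner, y increasing downwards; well boxes
#' are half-open `[min, max)` intervals.
#'
#' @param grid_rows,grid_cols Number of well rows/columns in the field of view.
#' @param well_pitch Centre-to-centre well spacing in pixels.
#' @param well_size Side of the bright inner square of a well, in pixels.
#'   Must be smaller than `well_pitch`.
#' @param wall_dark_frac Fractional darkening of the wall/shadow band relative
#'   to the well interior, in `[0, 1]`.
#' @param image_size Integer `c(height, width)` of the camera frame in pixels.
#' @param px_per_mm Spatial resolution; the default 80.6 px/mm corresponds to
#'   12.4 um per pixel.
#' @param margin Offset in pixels from the image edge to the first well's
#'   inner square (same for x and y).
#'
#' @return A `plate_config` list.
#' @export
plate_config <- function(grid_rows = 4L, grid_cols = 4L,
                         well_pitch = 160, well_size = 130,
                         wall_dark_frac = 0.5,
                         image_size = NULL, px_per_mm = 80.6,
                         margin = 20) {
  grid_rows <- as.integer(grid_rows)
  grid_cols <- as.integer(grid_cols)
  if (is.null(image_size)) {
    image_size <- c(
      grid_rows * well_pitch + 2 * margin,
      grid_cols * well_pitch + 2 * margin
    )
  }
  stopifnot(
    grid_rows >= 1L, grid_cols >= 1L,
    well_size > 0, well_size < well_pitch,
    wall_dark_frac >= 0, wall_dark_frac <= 1,
    px_per_mm > 0
  )
  if (grid_rows * well_pitch > image_size[1] ||
      grid_cols * well_pitch > image_size[2]) {
    stop("plate grid does not fit inside `image_size`", call. = FALSE)
  }
  structure(
    list(
      grid_rows = grid_rows, grid_cols = grid_cols,
      well_pitch = well_pitch, well_size = well_size,
      wall_dark_frac = wall_dark_frac,
      image_size = as.integer(image_size),
      px_per_mm = px_per_mm,
      margin = margin
    ),
    class = "plate_config"
  )
}

#' @exportS3Method base::print
print.plate_config <- function(x, ...) {
  cat(sprintf(
    "<plate_config> %dx%d wells, pitch %g px, well %g px, image %dx%d px, %.1f px/mm\n",
    x$grid_rows, x$grid_cols, x$well_pitch, x$well_size,
    x$image_size[1], x$image_size[2], x$px_per_mm
  ))
  invisible(x)
}

#' Worm kinematics configuration
#'
#' Parameters of the simulated worms: body geometry and a discrete-time
#' three-state Markov chain over the motion modes forward (`fw`), backward
#' (`bw`) and stationary (`st`), evaluated at frame resolution. During
#' light-on intervals of the stimulus schedule, transition probabilities
#' *into* the forward state are multiplied by `light_bias` and rows are
#' renormalised, which is the simulator's model of the blue-light escape
#' response.
#'
#' @param n_worms_per_well Worms placed per well (the standard assay uses 3).
#' @param body_length Worm body length in pixels (~1 mm at 12.4 um/px).
#' @param body_width Worm body width in pixels.
#' @param undulation_amplitude Amplitude of the sinusoidal midline in pixels.
#' @param undulation_wavelength Wavelength of the midline sinusoid in pixels.
#' @param mode_transition_matrix Row-stochastic 3x3 matrix over
#'   `c("fw","bw","st")`, applied once per frame.
#' @param light_bias Multiplier (>= 1) applied to transitions into `fw`
#'   during light-on intervals.
#' @param speed_fw,speed_bw Crawling speeds in pixels/s (both >= 0).
#' @param frame_rate Frames per second.
#' @param worm_contrast Worm pixel intensity relative to the well interior
#'   (dark worm on bright background).
#'
#' @return A `worm_kinematics` list.
#' @export
worm_kinematics <- function(n_worms_per_well = 3L,
                            body_length = 80,
                            body_width = 6,
                            undulation_amplitude = 6,
                            undulation_wavelength = 55,
                            mode_transition_matrix = default_mode_matrix(),
                            light_bias = 4,
                            speed_fw = 35, speed_bw = 25,
                            frame_rate = 25,
                            worm_contrast = 0.35) {
  P <- mode_transition_matrix
  stopifnot(
    is.matrix(P), all(dim(P) == c(3, 3)), all(P >= 0),
    speed_fw >= 0, speed_bw >= 0, light_bias >= 1, frame_rate > 0
  )
  if (any(abs(rowSums(P) - 1) > 1e-9)) {
    stop("each row of `mode_transition_matrix` must sum to 1", call. = FALSE)
  }
  dimnames(P) <- list(MOTION_MODES, MOTION_MODES)
  structure(
    list(
      n_worms_per_well = as.integer(n_worms_per_well),
      body_length = body_length, body_width = body_width,
      undulation_amplitude = undulation_amplitude,
      undulation_wavelength = undulation_wavelength,
      mode_transition_matrix = P,
      light_bias = light_bias,
      speed_fw = speed_fw, speed_bw = speed_bw,
      frame_rate = frame_rate,
      worm_contrast = worm_contrast
    ),
    class = "worm_kinematics"
  )
}

#' Motion mode labels
#'
#' Order is fixed: forward, backward, stationary.
#' @export
MOTION_MODES <- c("fw", "bw", "st")

#' Default per-frame motion-mode transition matrix
#'
#' Calibrated for 25 fps: forward bouts and pauses last on the order of ten
#' seconds, spontaneous reversals are brief (~1 s) and rare, roughly
#' matching unstimulated crawling on food.
#'
#' @return Row-stochastic 3x3 matrix over `c("fw","bw","st")`.
#' @export
default_mode_matrix <- function() {
  P <- rbind(
    fw = c(0.996, 0.001, 0.003),
    bw = c(0.020, 0.973, 0.007),
    st = c(0.003, 0.001, 0.996)
  )
  colnames(P) <- MOTION_MODES
  P
}

#' Stationary distribution of a motion-mode chain
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalised to
#' sum to 1.
#'
#' @param P Row-stochastic square matrix.
#' @return Named numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(v, rownames(P) %||% colnames(P))
}

#' Apply the light bias to a mode transition matrix
#'
#' Multiplies the column of transitions into `fw` by `light_bias`, then
#' renormalises each row to sum to 1.
#'
#' @param P Row-stochastic 3x3 matrix.
#' @param light_bias Multiplier >= 1.
#' @return Row-stochastic matrix.
#' @export
bias_mode_matrix <- function(P, light_bias) {
  stopifnot(light_bias >= 1)
  Q <- P
  Q[, "fw"] <- Q[, "fw"] * light_bias
  Q / rowSums(Q)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
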