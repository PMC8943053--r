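#' Well boxes for a plate configuration
#'
#' Enumerates the inner-square well boundaries of a plate lattice, row-major
#' from the top-left well. Boxes are half-open pixel intervals
#' `[x_min, x_max) x [y_min, y_max)` in 0-based image coordinates.
#'
#' @param plate A [plate_config()].
#' @param row_offset,col_offset Pixel position of the first well's inner
#'   square (top edge / left edge); default `plate$margin`.
#' @param camera_id Optional camera index in 1..6; if given, wells are named
#'   by their position on the full 96-well plate (see [camera_well_names()]),
#'   otherwise locally (`A1` top-left).
#' @return Tibble with `name`, `row`, `col`, `x_min`, `y_min`, `x_max`,
#'   `y_max`, `bad`.
#' @export
well_boxes <- function(plate, row_offset = NULL, col_offset = NULL,
                       camera_id = NULL) {
  row_offset <- row_offset %||% plate$margin
  col_offset <- col_offset %||% plate$margin
  g <- expand.grid(col = seq_len(plate$grid_cols), row = seq_len(plate$grid_rows))
  g <- g[order(g$row, g$col), ]
  nm <- if (is.null(camera_id)) {
    paste0(LETTERS[g$row], g$col)
  } else {
    camera_well_names(plate$grid_rows, plate$grid_cols, camera_id)
  }
  tibble::tibble(
    name = nm,
    row = g$row, col = g$col,
    x_min = col_offset + (g$col - 1) * plate$well_pitch,
    y_min = row_offset + (g$row - 1) * plate$well_pitch,
    x_max = col_offset + (g$col - 1) * plate$well_pitch + plate$well_size,
    y_max = row_offset + (g$row - 1) * plate$well_pitch + plate$well_size,
    bad = FALSE
  )
}

#' Well names for one camera of the array
#'
#' Six cameras tile the 96-well plate in 2 camera-rows x 3 camera-columns,
#' each seeing a `grid_rows` x `grid_cols` block (4x4 by default, so camera 1
#' sees wells A1..D4, camera 2 A5..D8, ..., camera 6 E9..H12). Names follow
#' the plate convention A1..H12, row-major within the block.
#'
#' @param grid_rows,grid_cols Block dimensions.
#' @param camera_id Integer in 1..6.
#' @return Character vector of length `grid_rows * grid_cols`.
#' @export
camera_well_names <- function(grid_rows, grid_cols, camera_id) {
  stopifnot(camera_id %in% 1:6)
  cam_row <- (camera_id - 1) %/% 3
  cam_col <- (camera_id - 1) %% 3
  rows <- cam_row * grid_rows + seq_len(grid_rows)
  cols <- cam_col * grid_cols + seq_len(grid_cols)
  g <- expand.grid(col = cols, row = rows)
  g <- g[order(g$row, g$col), ]
  paste0(LETTERS[g$row], g$col)
}

# 0/1 indicator, per pixel coordinate, of lying inside a well band along one
# axis (clamped lattice: only tiles 0..n-1 exist).
axis_in_band <- function(x, offset, pitch, size, n) {
  r <- x - offset
  j <- floor(r / pitch)
  r - j * pitch < size & j >= 0 & j < n
}

#' Render the static plate background
#'
#' Bright well interiors (intensity 1) on a darker wall/shadow band
#' (intensity `1 - wall_dark_frac`), with the lattice placed at the given
#' offsets. This is the noiseless, worm-free scene underlying every
#' simulated frame.
#'
#' @inheritParams well_boxes
#' @return Numeric matrix `image_size[1]` x `image_size[2]` with values in
#'   `[0, 1]`.
#' @export
render_background <- function(plate, row_offset = NULL, col_offset = NULL) {
  row_offset <- row_offset %||% plate$margin
  col_offset <- col_offset %||% plate$margin
  H <- plate$image_size[1]; W <- plate$image_size[2]
  in_y <- axis_in_band(0:(H - 1), row_offset, plate$well_pitch,
                       plate$well_size, plate$grid_rows)
  in_x <- axis_in_band(0:(W - 1), col_offset, plate$well_pitch,
                       plate$well_size, plate$grid_cols)
  low <- 1 - plate$wall_dark_frac
  low + (1 - low) * outer(in_y, in_x)
}

#' Intersection-over-union of two axis-aligned boxes
#'
#' Boxes are half-open `[x_min, x_max) x [y_min, y_max)`; vectorised over
#' rows of two data frames with those columns.
#'
#' @param a,b Data frames with columns `x_min`, `y_min`, `x_max`, `y_max`.
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ix <- pmax(0, pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min))
  iy <- pmax(0, pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min))
  inter <- ix * iy
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  inter / (area_a + area_b - inter)
}

# raw 8-bit frame <-> numeric [0, 255] matrix
frame_to_num <- function(frame) {
  if (is.raw(frame)) {
    d <- dim(frame)
    m <- matrix(as.integer(frame), nrow = d[1])
    storage.mode(m) <- "double"
    m
  } else {
    frame
  }
}

num_to_frame <- function(m) {
  r <- as.raw(pmin(255, pmax(0, round(m))))
  dim(r) <- dim(m)
  r
}
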