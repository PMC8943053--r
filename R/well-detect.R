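#' Build a single-well template image
#'
#' A bright inner square framed by a darker wall band, approximating the
#' appearance of one square well in brightfield: the well bottom is bright
#' and the dividing walls cast dark shadow bands. Values lie in `[0, 1]`.
#'
#' @param well_size Side of the bright inner square, pixels.
#' @param wall_dark_frac Darkening of the wall band (0 = no contrast).
#' @param pitch Side of the full template tile (well plus wall band);
#'   defaults to `well_size * 160 / 130`, the square-well plate ratio.
#' @return Numeric `pitch` x `pitch` matrix.
#' @export
build_template <- function(well_size, wall_dark_frac, pitch = NULL) {
  stopifnot(well_size >= 8)
  pitch <- round(pitch %||% (well_size * 160 / 130))
  stopifnot(pitch > well_size)
  lo <- (pitch - well_size) / 2
  x <- 0:(pitch - 1)
  inside <- x >= lo & x < lo + well_size
  low <- 1 - wall_dark_frac
  low + (1 - low) * outer(inside, inside)
}

#' Render a full lattice image from well-grid parameters
#'
#' The simulated grid of wells used by the fit objective: the well template
#' replicated on a lattice with the given offsets and pitches (clamped to
#' `grid_rows` x `grid_cols` tiles), normalised so the wall band is 0 and
#' the well interior 1.
#'
#' @param image_size `c(height, width)` pixels.
#' @param grid_rows,grid_cols Lattice dimensions.
#' @param row_offset,col_offset Pixel position of the first well's inner
#'   square.
#' @param row_pitch,col_pitch Centre-to-centre spacings, pixels.
#' @param well_frac Well inner size as a fraction of pitch.
#' @return Numeric 0/1 matrix.
#' @export
render_lattice <- function(image_size, grid_rows, grid_cols,
                           row_offset, col_offset, row_pitch, col_pitch,
                           well_frac = 130 / 160) {
  H <- image_size[1]; W <- image_size[2]
  in_y <- axis_in_band(0:(H - 1), row_offset, row_pitch,
                       well_frac * row_pitch, grid_rows)
  in_x <- axis_in_band(0:(W - 1), col_offset, col_pitch,
                       well_frac * col_pitch, grid_cols)
  outer(in_y, in_x) * 1
}

# Mean absolute difference between the min-max-normalised image and the
# normalised lattice, computed exactly via a summed-area table of
# g = |I - 1| - |I|: the lattice is 1 on a union of axis-aligned rectangles
# and 0 elsewhere, so the sum over the image decomposes into rectangle sums.
lattice_objective_factory <- function(image) {
  I <- frame_to_num(image)
  rng <- range(I)
  degenerate <- diff(rng) < .Machine$double.eps
  if (degenerate) {
    I <- matrix(0, nrow(I), ncol(I))
  } else {
    I <- (I - rng[1]) / diff(rng)
  }
  H <- nrow(I); W <- ncol(I)
  S0 <- sum(abs(I))
  g <- abs(I - 1) - abs(I)
  sat <- matrix(0, H + 1, W + 1)
  sat[-1, -1] <- apply(apply(g, 2, cumsum), 1, cumsum) |> t()
  npx <- H * W

  # integer pixel intervals of the well bands along one axis
  bands <- function(offset, pitch, size, n, dim_max) {
    start <- offset + (seq_len(n) - 1) * pitch
    lo <- pmax(0, ceiling(start))
    hi <- pmin(dim_max - 1, ceiling(start + size) - 1)
    keep <- hi >= lo
    cbind(lo[keep], hi[keep])
  }

  function(par, well_frac) {
    ro <- par[1]; co <- par[2]; rp <- par[3]; cp <- par[4]
    gr <- attr(par, "grid_rows"); gc <- attr(par, "grid_cols")
    by <- bands(ro, rp, well_frac * rp, gr, H)
    bx <- bands(co, cp, well_frac * cp, gc, W)
    tot <- S0
    if (nrow(by) && nrow(bx)) {
      for (i in seq_len(nrow(by))) {
        r0 <- by[i, 1]; r1 <- by[i, 2] + 1
        for (j in seq_len(nrow(bx))) {
          c0 <- bx[j, 1]; c1 <- bx[j, 2] + 1
          tot <- tot + sat[r1 + 1, c1 + 1] - sat[r0 + 1, c1 + 1] -
            sat[r1 + 1, c0 + 1] + sat[r0 + 1, c0 + 1]
        }
      }
    }
    tot / npx
  }
}

# Differential evolution (rand/1/bin) with box constraints.
de_optimize <- function(fn, lower, upper, seed = 0, np = 24, iters = 120,
                        f = 0.7, cr = 0.9, patience = 40) {
  set.seed(seed)
  d <- length(lower)
  pop <- matrix(stats::runif(np * d, lower, upper), nrow = np, byrow = TRUE)
  fit <- apply(pop, 1, fn)
  best_i <- which.min(fit)
  best <- pop[best_i, ]; best_f <- fit[best_i]
  stall <- 0L
  for (g in seq_len(iters)) {
    improved <- FALSE
    for (i in seq_len(np)) {
      r <- sample(setdiff(seq_len(np), i), 3)
      mut <- pop[r[1], ] + f * (pop[r[2], ] - pop[r[3], ])
      jr <- sample.int(d, 1)
      cross <- stats::runif(d) < cr
      cross[jr] <- TRUE
      trial <- ifelse(cross, mut, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      ft <- fn(trial)
      if (ft <= fit[i]) {
        pop[i, ] <- trial; fit[i] <- ft
        if (ft < best_f) {
          best_f <- ft; best <- trial; improved <- TRUE
        }
      }
    }
    stall <- if (improved) 0L else stall + 1L
    if (stall >= patience) break
  }
  list(par = best, value = best_f)
}

#' Fit the well lattice of a camera field of view
#'
#' Finds the lattice of wells in a grayscale frame (or static background) by
#' tiling a well template over a parameterised grid and minimising the mean
#' absolute intensity difference between the min-max-normalised image and
#' the simulated grid, using a differential-evolution optimiser with a
#' fixed seed. The optimised parameters are the two lattice offsets and the
#' two pitches; the grid dimensions come from configuration.
#'
#' @param image Numeric or raw matrix (grayscale frame).
#' @param grid_rows,grid_cols Known lattice dimensions.
#' @param bounds Optional named list of `c(min, max)` for `row_offset`,
#'   `col_offset`, `row_pitch`, `col_pitch`; sensible defaults are derived
#'   from the image size.
#' @param seed Optimiser seed; fixed seed gives an identical fit.
#' @param well_frac Well inner size as a fraction of pitch (from plate
#'   configuration).
#' @param residual_ceiling Residual above which the fit is flagged low
#'   confidence (not an error).
#' @param camera_id Optional camera index for plate-level well naming.
#' @return A `well_grid`: lattice parameters, `wells` tibble (name, box,
#'   bad flag), `fit_residual`, and `low_confidence` flag.
#' @export
fit_lattice <- function(image, grid_rows = 4, grid_cols = 4, bounds = NULL,
                        seed = 0, well_frac = 130 / 160,
                        residual_ceiling = 0.3, camera_id = NULL) {
  I <- frame_to_num(image)
  H <- nrow(I); W <- ncol(I)
  if (H / grid_rows < 10 || W / grid_cols < 10) {
    stop("image too small for the requested grid", call. = FALSE)
  }
  min_pitch_r <- max(10, 0.6 * H / grid_rows)
  min_pitch_c <- max(10, 0.6 * W / grid_cols)
  b <- list(
    row_offset = c(0, 0.3 * H),
    col_offset = c(0, 0.3 * W),
    row_pitch = c(min_pitch_r, H / grid_rows),
    col_pitch = c(min_pitch_c, W / grid_cols)
  )
  if (!is.null(bounds)) b[names(bounds)] <- bounds
  obj0 <- lattice_objective_factory(I)
  obj <- function(par) {
    attr(par, "grid_rows") <- grid_rows
    attr(par, "grid_cols") <- grid_cols
    obj0(par, well_frac)
  }
  lower <- vapply(b, `[`, 0, 1)[c("row_offset", "col_offset", "row_pitch", "col_pitch")]
  upper <- vapply(b, `[`, 0, 2)[c("row_offset", "col_offset", "row_pitch", "col_pitch")]
  degenerate <- diff(range(I)) < .Machine$double.eps
  fit <- de_optimize(obj, lower, upper, seed = seed)
  par <- fit$par
  plate_like <- list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    well_pitch = NA, well_size = NA, margin = NA
  )
  g <- expand.grid(col = seq_len(grid_cols), row = seq_len(grid_rows))
  g <- g[order(g$row, g$col), ]
  nm <- if (is.null(camera_id)) paste0(LETTERS[g$row], g$col) else
    camera_well_names(grid_rows, grid_cols, camera_id)
  wells <- tibble::tibble(
    name = nm, row = g$row, col = g$col,
    x_min = par[2] + (g$col - 1) * par[4],
    y_min = par[1] + (g$row - 1) * par[3],
    x_max = par[2] + (g$col - 1) * par[4] + well_frac * par[4],
    y_max = par[1] + (g$row - 1) * par[3] + well_frac * par[3],
    bad = FALSE,
    bad_reason = NA_character_
  )
  structure(
    list(
      row_offset = par[1], col_offset = par[2],
      row_pitch = par[3], col_pitch = par[4],
      grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
      well_frac = well_frac,
      wells = wells,
      fit_residual = fit$value,
      low_confidence = degenerate || fit$value > residual_ceiling,
      objective = obj
    ),
    class = "well_grid"
  )
}

#' @exportS3Method base::print
print.well_grid <- function(x, ...) {
  cat(sprintf(
    "<well_grid> %dx%d wells, pitch (%.1f, %.1f) px, offset (%.1f, %.1f), residual %.4f%s\n",
    x$grid_rows, x$grid_cols, x$row_pitch, x$col_pitch,
    x$row_offset, x$col_offset, x$fit_residual,
    if (x$low_confidence) " [LOW CONFIDENCE]" else ""
  ))
  invisible(x)
}

#' Map a point to its well
#'
#' Returns the name of the well whose half-open inner box contains the
#' point, or `NA` for points on a wall band or outside the lattice.
#'
#' @param grid A `well_grid` (or the truth `wells` tibble).
#' @param x,y Point coordinates in pixels (vectorised).
#' @return Character vector of well names (`NA` = no well).
#' @export
locate_point <- function(grid, x, y) {
  wells <- if (inherits(grid, "well_grid")) grid$wells else grid
  out <- rep(NA_character_, length(x))
  for (i in seq_len(nrow(wells))) {
    hit <- x >= wells$x_min[i] & x < wells$x_max[i] &
      y >= wells$y_min[i] & y < wells$y_max[i]
    out[hit] <- wells$name[i]
  }
  out
}

#' Flag a well as bad
#'
#' Marks a well (for contamination, damage, or liquid problems) so that
#' every downstream per-well output carries the flag and the well is
#' excluded from aggregates. Idempotent.
#'
#' @param grid A `well_grid`.
#' @param name Well name (must exist in the grid).
#' @param reason Free-text reason recorded with the flag.
#' @return The modified `well_grid`.
#' @export
mark_bad_well <- function(grid, name, reason = "manual") {
  i <- match(name, grid$wells$name)
  if (anyNA(i)) {
    stop("unknown well name: ", paste(name[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  grid$wells$bad[i] <- TRUE
  grid$wells$bad_reason[i] <- reason
  grid
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.well_grid <- function(x, ...) x$wells

#' @export
glance.well_grid <- function(x, ...) {
  tibble::tibble(
    grid_rows = x$grid_rows, grid_cols = x$grid_cols,
    row_pitch = x$row_pitch, col_pitch = x$col_pitch,
    row_offset = x$row_offset, col_offset = x$col_offset,
    fit_residual = x$fit_residual,
    low_confidence = x$low_confidence,
    n_bad_wells = sum(x$wells$bad)
  )
}

#' @export
autoplot.well_grid <- function(object, image = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(image)) {
    I <- frame_to_num(image)
    df <- expand.grid(y = seq_len(nrow(I)) - 1, x = seq_len(ncol(I)) - 1)
    df$value <- as.vector(I)
    p <- p + ggplot2::geom_raster(
      data = df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)
    ) +
      ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none")
  }
  p +
    ggplot2::geom_rect(
      data = object$wells,
      ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                   ymin = .data$y_min, ymax = .data$y_max,
                   colour = .data$bad),
      fill = NA, linewidth = 0.4
    ) +
    ggplot2::geom_text(
      data = object$wells,
      ggplot2::aes(x = (.data$x_min + .data$x_max) / 2,
                   y = (.data$y_min + .data$y_max) / 2,
                   label = .data$name),
      colour = "red", size = 3
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "green3", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}
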