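test_that("well template is a bright square framed by a darker wall", {
  tpl <- build_template(130, 0.5)
  ctr <- tpl[nrow(tpl) %/% 2, ncol(tpl) %/% 2]
  expect_gt(ctr, tpl[1, 1])
  expect_true(all(tpl >= 0 & tpl <= 1))
  # zero wall contrast degenerates to a constant image
  expect_equal(diff(range(build_template(130, 0))), 0)
})

test_that("lattice rendered at truth parameters matches the synthetic frame", {
  pf <- render_plate_frame(seed = 2, with_worms = FALSE)
  lat <- render_lattice(dim(pf$frame), 4, 4,
                        pf$row_offset, pf$col_offset, 160, 160)
  I <- pf$frame / 255
  I <- (I - min(I)) / diff(range(I))
  expect_lt(mean(abs(I - lat)), 0.05)
})

test_that("summed-area objective equals the naive tiled-template objective", {
  pf <- render_plate_frame(plate_config(grid_rows = 2, grid_cols = 2),
                           seed = 4, noise_sd = 0.02)
  g <- fit_lattice(pf$frame, 2, 2, seed = 1)
  naive <- function(par) {
    I <- pf$frame
    I <- (I - min(I)) / diff(range(I))
    lat <- render_lattice(dim(I), 2, 2, par[1], par[2], par[3], par[4])
    mean(abs(I - lat))
  }
  for (par in list(c(20, 20, 160, 160), c(11.3, 25.8, 150.1, 170.7),
                   c(0, 0, 100, 100))) {
    p <- par
    attr(p, "grid_rows") <- 2L
    attr(p, "grid_cols") <- 2L
    expect_equal(g$objective(p), naive(par), tolerance = 1e-12)
  }
})

test_that("lattice fit recovers the truth geometry on synthetic frames", {
  pf <- render_plate_frame(seed = 0, noise_sd = 0.02)
  g <- fit_lattice(pf$frame, 4, 4, seed = 0)
  expect_equal(nrow(g$wells), 16)
  expect_true(all(box_iou(g$wells, pf$wells) >= 0.9))
  expect_false(g$low_confidence)

  # noiseless frame without worms: pitch recovered within 1 px
  pf0 <- render_plate_frame(seed = 1, with_worms = FALSE)
  g0 <- fit_lattice(pf0$frame, 4, 4, seed = 0)
  expect_lt(abs(g0$row_pitch - 160), 1)
  expect_lt(abs(g0$col_pitch - 160), 1)
  # optimiser adequacy: fitted objective no worse than the truth parameters
  truth_par <- c(pf0$row_offset, pf0$col_offset, 160, 160)
  attr(truth_par, "grid_rows") <- 4L
  attr(truth_par, "grid_cols") <- 4L
  expect_lte(g0$fit_residual, g0$objective(truth_par) + 1e-6)
})

test_that("a structureless frame is flagged low confidence, small images error", {
  flat <- matrix(128, 400, 400)
  g <- fit_lattice(flat, 4, 4, seed = 0)
  expect_true(g$low_confidence)
  expect_error(fit_lattice(matrix(0, 20, 20), 4, 4), "too small")
})

test_that("fixed seed gives an identical fitted grid", {
  pf <- render_plate_frame(seed = 3, noise_sd = 0.03)
  g1 <- fit_lattice(pf$frame, 4, 4, seed = 11)
  g2 <- fit_lattice(pf$frame, 4, 4, seed = 11)
  g1$objective <- g2$objective <- NULL
  expect_identical(g1[names(g1) != "wells"], g2[names(g2) != "wells"])
  expect_identical(as.data.frame(g1$wells), as.data.frame(g2$wells))
})

test_that("locate_point maps well centres, walls, and truth worms correctly", {
  pf <- render_plate_frame(seed = 0, noise_sd = 0.01)
  g <- fit_lattice(pf$frame, 4, 4, seed = 0)
  w <- g$wells[g$wells$name == "A1", ]
  expect_equal(locate_point(g, (w$x_min + w$x_max) / 2,
                            (w$y_min + w$y_max) / 2), "A1")
  # a point on the shared wall band between A1 and A2 maps to no well
  expect_true(is.na(locate_point(g, w$x_max + 1, (w$y_min + w$y_max) / 2)))
  expect_true(is.na(locate_point(g, -5, -5)))

  ses <- tiny_session()
  gf <- fit_lattice(ses$store$frames[[1]], 2, 2, seed = 0)
  worms <- ses$truth[ses$truth$label == "worm", ]
  mapped <- locate_point(gf, worms$x, worms$y)
  expect_equal(mean(mapped == worms$well), 1)
})

test_that("bad-well flags propagate and are idempotent", {
  pf <- render_plate_frame(seed = 0)
  g <- fit_lattice(pf$frame, 4, 4, seed = 0)
  g2 <- mark_bad_well(g, "B2", "contamination")
  expect_true(g2$wells$bad[g2$wells$name == "B2"])
  g3 <- mark_bad_well(g2, "B2")
  expect_identical(g2$wells$bad, g3$wells$bad)
  expect_error(mark_bad_well(g, "Z9"), "unknown well")
  expect_equal(sum(glance(g2)$n_bad_wells), 1)
})

test_that("tidy and glance expose the fitted lattice", {
  pf <- render_plate_frame(seed = 0)
  g <- fit_lattice(pf$frame, 4, 4, seed = 0)
  expect_s3_class(tidy(g), "tbl_df")
  expect_equal(nrow(tidy(g)), 16)
  expect_named(glance(g),
               c("grid_rows", "grid_cols", "row_pitch", "col_pitch",
                 "row_offset", "col_offset", "fit_residual",
                 "low_confidence", "n_bad_wells"))
})
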