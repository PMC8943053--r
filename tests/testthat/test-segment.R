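test_that("three separated worms give three objects near truth centroids", {
  sched <- build_schedule("custom",
                          segments = data.frame(label = "off", duration = 0.04))
  ses <- simulate_session(
    plate_config(grid_rows = 1, grid_cols = 1,
                 image_size = c(200, 200), margin = 35),
    worm_kinematics(), sched, seed = 7
  )
  d <- segment_frame(ses$store$frames[[1]], frame_number = 0)
  expect_equal(nrow(d), 3)
  tru <- ses$truth[ses$truth$frame == 0, ]
  for (i in seq_len(nrow(d))) {
    err <- min(sqrt((tru$x - d$x[i])^2 + (tru$y - d$y[i])^2))
    expect_lt(err, 2)
  }
})

test_that("blank frames and sub-threshold objects give empty results", {
  blank <- matrix(255, 120, 120)
  expect_equal(nrow(segment_frame(blank)), 0)
  # a small dark blob below min_area is excluded
  blank[60:62, 60:62] <- 50
  expect_equal(nrow(segment_frame(blank, segment_params(min_area = 60))), 0)
  expect_equal(nrow(segment_frame(blank, segment_params(min_area = 5))), 1)
})

test_that("mask_frame zeroes exactly the pixels beyond the halo", {
  fr <- matrix(200, 60, 60)
  fr[30:32, 30:34] <- 40
  d <- segment_frame(fr, segment_params(min_area = 5))
  masked <- mask_frame(fr, d, halo = 5)
  # independent oracle: brute-force euclidean distance to the object pixels
  obj <- which(fr == 40, arr.ind = TRUE)
  for (p in list(c(31, 32), c(25, 32), c(31, 45), c(1, 1))) {
    dmin <- min(sqrt((obj[, 1] - p[1])^2 + (obj[, 2] - p[2])^2))
    if (dmin > 5) {
      expect_equal(masked[p[1], p[2]], 0)
    } else {
      expect_equal(masked[p[1], p[2]], fr[p[1], p[2]])
    }
  }
  # idempotence and degenerate cases
  expect_identical(mask_frame(masked, d, halo = 5), masked)
  expect_equal(sum(mask_frame(fr, d[0, ], halo = 5)), 0)
  expect_identical(mask_frame(fr, d, halo = 100), fr * 1)
})

test_that("linking: continuity, gap rule, and detection conservation", {
  # one object moving < max_step per frame -> one track
  det <- tibble::tibble(
    frame = 0:9, x = seq(0, 18, by = 2), y = 5,
    area = 100L, x_min = 0, y_min = 0, x_max = 10, y_max = 10,
    mask = replicate(10, matrix(TRUE, 2, 2), simplify = FALSE),
    midline = replicate(10, cbind(x = 1:3, y = 1), simplify = FALSE),
    length = 2
  )
  tr <- link_tracks(det, max_step = 5)
  expect_equal(dplyr::n_distinct(tr$track_id), 1)

  # a 10-frame disappearance splits the track in two
  det_gap <- det
  det_gap$frame <- c(0:3, 14:19)
  tr2 <- link_tracks(det_gap, max_step = 5)
  expect_equal(dplyr::n_distinct(tr2$track_id), 2)

  # conservation: every detection belongs to exactly one track
  expect_equal(nrow(tr2), nrow(det_gap))
  expect_false(anyNA(tr2$track_id))

  # jumps beyond max_step start new tracks
  det3 <- det
  det3$x <- c(0, 2, 50, 52, 54, 100, 102, 104, 106, 108)
  tr3 <- link_tracks(det3, max_step = 5)
  expect_equal(dplyr::n_distinct(tr3$track_id), 3)
})

test_that("no-crossing session: tracks never mix truth worms", {
  tr <- solo_tracks()
  ses <- solo_session()
  expect_gte(dplyr::n_distinct(tr$track_id),
             dplyr::n_distinct(ses$truth$object_id))
  mm <- match_tracks_to_truth(tr, ses$truth)
  expect_true(all(mm$tracks$truth_class == "worm"))
})

test_that("motion modes recover the simulator truth on a solo worm", {
  tr <- solo_tracks()
  ses <- solo_session()
  joined <- dplyr::inner_join(
    tr[, c("frame", "mode")], ses$truth[, c("frame", "mode")],
    by = "frame", suffix = c("_est", "_tru")
  )
  acc <- mean(as.character(joined$mode_est) == as.character(joined$mode_tru),
              na.rm = TRUE)
  expect_gte(acc, 0.95)
})

test_that("a forced-forward worm is labelled forward almost everywhere", {
  P <- matrix(c(1, 0, 0), 3, 3, byrow = FALSE) # every row jumps to fw
  P <- cbind(1, 0, 0)[rep(1, 3), ]
  sched <- build_schedule("custom",
                          segments = data.frame(label = "off", duration = 6))
  ses <- simulate_session(
    plate_config(grid_rows = 1, grid_cols = 1,
                 image_size = c(200, 200), margin = 35),
    worm_kinematics(n_worms_per_well = 1, mode_transition_matrix = P),
    sched, seed = 13
  )
  tr <- track_session(ses$store, ses$wells)
  expect_gte(mean(tr$mode == "fw", na.rm = TRUE), 0.95)
})

test_that("a static object is stationary and time reversal swaps fw/bw", {
  st <- straight_static_track()
  cl <- classify_motion(st[, setdiff(names(st), c("mode", "signed_speed"))],
                        frame_rate = 25)
  expect_true(all(cl$mode == "st"))

  # a straight moving track with fixed head-first midlines
  n <- 40
  mls <- lapply(seq_len(n), function(k) {
    cbind(x = seq(k + 60, k, length.out = 31), y = 40) # head at larger x
  })
  mv <- tibble::tibble(
    track_id = 1L, frame = seq_len(n) - 1L,
    x = vapply(mls, function(m) mean(m[, 1]), 0), y = 40,
    area = 300L, length = 60,
    midline = mls
  )
  fwd <- classify_motion(mv, frame_rate = 25)
  rev_tr <- mv
  rev_tr$x <- rev(mv$x)
  rev_tr$midline <- rev(mv$midline)
  bwd <- classify_motion(rev_tr, frame_rate = 25)
  expect_true(all(fwd$mode == "fw"))
  expect_true(all(bwd$mode == "bw"))
})

test_that("tracks are assigned to wells by median centroid, walls discarded", {
  ses <- tiny_session()
  tr <- solo_tracks()
  # synthetic tracks: one centred in a well, one on a wall band
  wells <- ses$wells
  mk <- function(id, x, y) tibble::tibble(
    track_id = id, frame = 0:4, x = x, y = y
  )
  inside <- mk(1L, (wells$x_min[1] + wells$x_max[1]) / 2,
               (wells$y_min[1] + wells$y_max[1]) / 2)
  on_wall <- mk(2L, wells$x_max[1] + 2, (wells$y_min[1] + wells$y_max[1]) / 2)
  out <- assign_tracks(dplyr::bind_rows(inside, on_wall), ses$wells)
  expect_equal(unique(out$well[out$track_id == 1]), wells$name[1])
  expect_false(2L %in% out$track_id)
  expect_equal(attr(out, "discarded_tracks"), 1L)

  # bad-well flag propagates to tracks
  wells_bad <- wells
  wells_bad$bad[1] <- TRUE
  out2 <- assign_tracks(inside, wells_bad)
  expect_true(all(out2$bad))
})
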