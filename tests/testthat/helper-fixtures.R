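# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# a short rendered 2x2-well session with 3 worms/well
tiny_session <- function() {
  memo("tiny_session", {
    sched <- build_schedule("custom",
                            segments = data.frame(label = "off", duration = 4))
    simulate_session(plate_config(grid_rows = 2, grid_cols = 2),
                     worm_kinematics(), sched, seed = 5)
  })
}

# a single-well single-worm session (no crossings)
solo_session <- function() {
  memo("solo_session", {
    sched <- build_schedule("custom",
                            segments = data.frame(label = "off", duration = 8))
    simulate_session(
      plate_config(grid_rows = 1, grid_cols = 1,
                   image_size = c(200, 200), margin = 35),
      worm_kinematics(n_worms_per_well = 1), sched, seed = 3
    )
  })
}

solo_tracks <- function() {
  memo("solo_tracks", {
    ses <- solo_session()
    track_session(ses$store, ses$wells)
  })
}

# a synthetic straight, static "worm" track built directly (no rendering):
# horizontal bar of known length and area
straight_static_track <- function(n_frames = 20, length_px = 60,
                                  width_px = 5, well = "A1") {
  ml <- cbind(x = seq(20, 20 + length_px, by = 1), y = 40)
  tibble::tibble(
    track_id = 1L,
    frame = seq_len(n_frames) - 1L,
    t = (seq_len(n_frames) - 1) / 25,
    x = mean(ml[, 1]), y = 40,
    area = as.integer(length_px * width_px),
    length = length_px,
    signed_speed = 0,
    mode = factor("st", levels = MOTION_MODES),
    midline = replicate(n_frames, ml, simplify = FALSE),
    well = well,
    bad = FALSE
  )
}

# matrix power, used as a brute-force oracle for stationary distributions
`%^%` <- function(P, n) {
  out <- diag(nrow(P))
  for (i in seq_len(n)) out <- out %*% P
  out
}
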