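test_that("mode fractions normalise by tracked worms and sum to one", {
  tr <- tibble::tibble(
    well = "A1", t = 0,
    mode = factor(c("fw", "fw", "st"), levels = MOTION_MODES)
  )
  mf <- mode_fractions(tr)
  expect_equal(mf$f_fw, 2 / 3)
  expect_equal(mf$f_st, 1 / 3)
  expect_equal(mf$f_bw, 0)
  expect_equal(mf$n_tracked, 3L)

  # zero tracked worms (all modes undefined) -> no row, not zeros
  tr2 <- tibble::tibble(
    well = "A1", t = c(0, 1),
    mode = factor(c("fw", NA), levels = MOTION_MODES)
  )
  mf2 <- mode_fractions(tr2)
  expect_equal(nrow(mf2), 1)
  expect_equal(mf2$t, 0)

  # bad wells are excluded
  tr3 <- dplyr::mutate(tr, bad = TRUE)
  expect_equal(nrow(mode_fractions(tr3)), 0)

  # conservation at every defined point of a simulated population
  tr4 <- simulate_mode_tracks(
    4, worm_kinematics(),
    build_schedule("custom", segments = data.frame(label = "off", duration = 5)),
    seed = 2
  )
  mf4 <- mode_fractions(tr4)
  expect_true(all(abs(mf4$f_fw + mf4$f_bw + mf4$f_st - 1) < 1e-9))
})

test_that("light pulses raise the forward fraction above baseline", {
  sched <- build_schedule("standard")
  tr <- simulate_mode_tracks(16, worm_kinematics(light_bias = 6), sched,
                             seed = 4, frame_rate = 5)
  mf <- mode_fractions(tr)
  lit <- light_on(sched, mf$t)
  tt <- stats::t.test(mf$f_fw[lit], mf$f_fw[mf$t < 300],
                      alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("bootstrap aggregation: degenerate CIs, containment, reproducibility", {
  base <- tibble::tibble(
    well = rep(c("A1", "A2", "A3"), each = 2),
    t = rep(c(0, 1), 3),
    n_tracked = 3L, f_fw = 0.5, f_bw = 0.2, f_st = 0.3
  )
  agg <- aggregate_bootstrap(base, n_boot = 50, seed = 1)
  expect_true(all(agg$hi - agg$lo == 0)) # identical wells
  expect_true(all(agg$lo <= agg$mean & agg$mean <= agg$hi))

  varied <- base
  set.seed(9)
  varied$f_fw <- stats::runif(6)
  a1 <- aggregate_bootstrap(varied, n_boot = 100, seed = 7)
  a2 <- aggregate_bootstrap(varied, n_boot = 100, seed = 7)
  expect_identical(a1, a2)
  expect_true(all(a1$lo <= a1$mean + 1e-12 & a1$mean <= a1$hi + 1e-12))

  expect_error(aggregate_bootstrap(base[base$well == "A1", ]), "2 wells")
})

test_that("prevalent-mode downsampling takes the window majority with st-priority ties", {
  mk <- function(modes) tibble::tibble(
    well = "A1", worm_id = 1L, t = (seq_along(modes) - 1) / 25,
    mode = factor(modes, levels = MOTION_MODES)
  )
  # 50 frames at 25 fps: 30 fw + 20 st in one 2-s window -> fw
  expect_equal(as.character(downsample_prevalent(mk(rep(c("fw", "st"), c(30, 20))))$mode), "fw")
  # 25/25 tie -> st (conservative tie rule)
  expect_equal(as.character(downsample_prevalent(mk(rep(c("fw", "st"), c(25, 25))))$mode), "st")
  # constant series stays constant, at 0.5 Hz
  const <- mk(rep("bw", 100))
  ds <- downsample_prevalent(const)
  expect_true(all(ds$mode == "bw"))
  expect_equal(nrow(ds), 2)
  expect_equal(ds$t, c(0, 2))
  # all-undefined window -> undefined sample
  und <- mk(rep(NA_character_, 50))
  expect_true(is.na(downsample_prevalent(und)$mode))
})

test_that("pulse deltas: zero for constant series, mode-sum conservation, window rule", {
  sched <- build_schedule("standard")
  ts <- seq(0, 959)
  const <- tibble::tibble(
    t = rep(ts, 3),
    mode = factor(rep(MOTION_MODES, each = length(ts)), levels = MOTION_MODES),
    mean = rep(c(0.5, 0.2, 0.3), each = length(ts))
  )
  pd <- pulse_response_delta(const, sched)
  expect_equal(nrow(pd), 9)
  expect_true(all(pd$delta == 0))

  # arbitrary series: per-pulse deltas over modes sum to zero when the
  # fractions sum to one
  set.seed(3)
  f <- matrix(stats::runif(3 * length(ts)), ncol = 3)
  f <- f / rowSums(f)
  varied <- tibble::tibble(
    t = rep(ts, 3),
    mode = factor(rep(MOTION_MODES, each = length(ts)), levels = MOTION_MODES),
    mean = as.vector(f)
  )
  pdv <- pulse_response_delta(varied, sched)
  sums <- tapply(pdv$delta, pdv$pulse, sum)
  expect_true(all(abs(sums) < 1e-9))

  # a pulse whose window leaves the recording is skipped with a warning
  short <- varied[varied$t < 575, ]
  expect_warning(pulse_response_delta(short, sched), "skipped")
})

test_that("sensitisation: growing per-pulse bias gives increasing fw deltas", {
  sched <- build_schedule("serial")
  tr <- simulate_mode_tracks(
    24, worm_kinematics(), sched, seed = 6, frame_rate = 25,
    light_bias_by_pulse = seq(1.5, 12, length.out = 20)
  )
  agg <- aggregate_bootstrap(mode_fractions(tr), n_boot = 20, seed = 1)
  pd <- pulse_response_delta(agg, sched)
  fw <- pd[pd$mode == "fw", ]
  ct <- suppressWarnings(
    stats::cor.test(fw$pulse, fw$delta, method = "spearman",
                    alternative = "greater")
  )
  expect_lt(ct$p.value, 0.05)
})

test_that("baseline shift: zero-sum, null behaviour, and fatigue", {
  sched <- build_schedule("custom",
                          segments = data.frame(label = "off", duration = 700))
  # null: stationary chain, no light -> shifts within 3 SE of zero
  tr <- simulate_mode_tracks(24, worm_kinematics(light_bias = 1), sched,
                             seed = 8, frame_rate = 2)
  mf <- mode_fractions(tr)
  agg <- aggregate_bootstrap(mf, n_boot = 20, seed = 1)
  bs <- baseline_shift(agg, sched)
  expect_lt(abs(sum(bs$shift)), 1e-9)
  # SE of the shift from per-well first/last window differences
  per_well <- mf |>
    dplyr::group_by(well) |>
    dplyr::summarise(d = mean(f_st[t >= 400]) - mean(f_st[t < 300]))
  se <- stats::sd(per_well$d) / sqrt(nrow(per_well))
  expect_lt(abs(bs$shift[bs$mode == "st"]), 3 * se)

  # fatigue: a pause-biased chain in the final stretch raises the st fraction
  wk_tired <- worm_kinematics(mode_transition_matrix = rbind(
    fw = c(0.97, 0.001, 0.029),
    bw = c(0.02, 0.973, 0.007),
    st = c(0.001, 0.001, 0.998)
  ))
  tr1 <- simulate_mode_tracks(24, worm_kinematics(light_bias = 1), sched,
                              seed = 9, frame_rate = 2)
  tr2 <- simulate_mode_tracks(24, wk_tired,
                              build_schedule("custom",
                                             segments = data.frame(label = "off", duration = 700)),
                              seed = 10, frame_rate = 2)
  tr2$t <- tr2$t + 700
  both <- dplyr::bind_rows(tr1, tr2)
  sched2 <- build_schedule("custom",
                           segments = data.frame(label = "off", duration = 1400))
  agg2 <- aggregate_bootstrap(mode_fractions(both), n_boot = 20, seed = 2)
  bs2 <- baseline_shift(agg2, sched2)
  expect_gt(bs2$shift[bs2$mode == "st"], 0)

  expect_error(baseline_shift(agg, build_schedule("custom",
                                                  segments = data.frame(label = "off", duration = 400))),
               "shorter")
})
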