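test_that("well ranges expand to rectangular blocks and lists", {
  expect_length(expand_well_range("A1-B12"), 24)
  expect_equal(expand_well_range("A1-B2"), c("A1", "A2", "B1", "B2"))
  expect_equal(expand_well_range("A1,A3,B7"), c("A1", "A3", "B7"))
  expect_equal(expand_well_range("C5"), "C5")
  expect_error(expand_well_range("A0"), "outside")
  expect_error(expand_well_range("A1-B2-C3"), "malformed")
  expect_error(expand_well_range("Q1"), "malformed")
})

test_that("plate metadata compilation joins compounds through the robot map", {
  fx <- make_metadata_fixtures(seed = 3, n_plates = 2, shuffle = TRUE)
  pm <- compile_plate_metadata(fx$files$wormsorter, fx$files$sourceplate,
                               fx$files$robotlog)
  expect_equal(nrow(pm), 2 * 96)
  # column-shuffle round trip: compound of the imaging well equals the
  # compound of the mapped source well, via the inverse permutation
  for (p in unique(pm$imaging_plate_id)) {
    perm <- fx$column_map[[p]]
    sub <- pm[pm$imaging_plate_id == p, ]
    img_col <- as.integer(substring(sub$well_name, 2))
    src_col <- match(img_col, perm)
    expect_equal(sub$compound_name, sprintf("compound_%02d", src_col))
    expect_equal(sub$source_well,
                 paste0(substring(sub$well_name, 1, 1), src_col))
  }

  # without compound records the compound columns stay empty
  pm0 <- compile_plate_metadata(fx$files$wormsorter)
  expect_true(all(is.na(pm0$compound_name)))

  # overlapping ranges are rejected
  ws_bad <- fx$files$wormsorter
  ws_bad$well_range[2] <- "D1-E12" # overlaps the A1-D12 block
  expect_error(compile_plate_metadata(ws_bad), "overlapping")

  # robotlog referencing unseeded wells is rejected with the wells listed
  ws_half <- fx$files$wormsorter[fx$files$wormsorter$well_range == "A1-D12", ]
  expect_error(
    compile_plate_metadata(ws_half, fx$files$sourceplate, fx$files$robotlog),
    "absent from wormsorter"
  )
})

test_that("final metadata reproduces the fixture oracle byte for byte", {
  fx <- make_metadata_fixtures(seed = 3, n_plates = 2, shuffle = TRUE)
  pm <- compile_plate_metadata(fx$files$wormsorter, fx$files$sourceplate,
                               fx$files$robotlog)
  fin <- compile_final_metadata(pm, fx$files$manual_metadata,
                                fx$files$recordings)
  expect_identical(as.data.frame(fin), as.data.frame(fx$expected))
  # 2 plates x 6 videos x 16 wells
  expect_equal(nrow(fin), 192)
  expect_equal(unname(table(fin$video)[1]), 16)

  # identity mapping (no robot) and no compounds also round-trip
  fx2 <- make_metadata_fixtures(seed = 4, shuffle = FALSE,
                                with_compounds = FALSE)
  pm2 <- compile_plate_metadata(fx2$files$wormsorter)
  fin2 <- compile_final_metadata(pm2, fx2$files$manual_metadata,
                                 fx2$files$recordings)
  expect_identical(as.data.frame(fin2), as.data.frame(fx2$expected))

  # identity imaging2source attaches compounds without shuffling
  fx3 <- make_metadata_fixtures(seed = 5, shuffle = FALSE)
  pm3 <- compile_plate_metadata(fx3$files$wormsorter, fx3$files$sourceplate,
                                imaging2source = fx3$files$imaging2source)
  fin3 <- compile_final_metadata(pm3, fx3$files$manual_metadata,
                                 fx3$files$recordings)
  expect_identical(as.data.frame(fin3), as.data.frame(fx3$expected))
})

test_that("the CSV file path gives identical results to in-memory tables", {
  dir <- withr::local_tempdir()
  fx <- make_metadata_fixtures(seed = 6, n_plates = 1, dir = dir)
  pm <- compile_plate_metadata(file.path(dir, "wormsorter.csv"),
                               file.path(dir, "sourceplate.csv"),
                               file.path(dir, "robotlog.csv"))
  fin <- compile_final_metadata(pm, file.path(dir, "manual_metadata.csv"),
                                file.path(dir, "recordings.csv"))
  expect_identical(as.data.frame(fin), as.data.frame(fx$expected))
})

test_that("final-metadata join errors are hard and informative", {
  fx <- make_metadata_fixtures(seed = 7)
  pm <- compile_plate_metadata(fx$files$wormsorter, fx$files$sourceplate,
                               fx$files$robotlog)
  mm_dup <- dplyr::bind_rows(fx$files$manual_metadata,
                             fx$files$manual_metadata)
  expect_error(compile_final_metadata(pm, mm_dup, fx$files$recordings),
               "duplicate")
  rec_orphan <- fx$files$recordings
  rec_orphan$run_number[1] <- 99L
  expect_error(compile_final_metadata(pm, fx$files$manual_metadata,
                                      rec_orphan),
               "no manual-metadata")
})

test_that("bad-well flags join into the final metadata", {
  fx <- make_metadata_fixtures(seed = 8)
  pm <- compile_plate_metadata(fx$files$wormsorter, fx$files$sourceplate,
                               fx$files$robotlog)
  bw <- tibble::tibble(video = fx$files$recordings$video[1],
                       well_name = "A1")
  fin <- compile_final_metadata(pm, fx$files$manual_metadata,
                                fx$files$recordings, bad_wells = bw)
  expect_equal(sum(fin$well_label_bad), 1)
  expect_true(fin$well_label_bad[fin$video == bw$video &
                                   fin$well_name == "A1"])
})

test_that("metadata validation reports violations machine-readably", {
  fx <- make_metadata_fixtures(seed = 9)
  pm <- compile_plate_metadata(fx$files$wormsorter, fx$files$sourceplate,
                               fx$files$robotlog)
  fin <- compile_final_metadata(pm, fx$files$manual_metadata,
                                fx$files$recordings)
  expect_equal(validate_metadata(fin)$n_violations, 0)
  # injected duplicate
  v1 <- validate_metadata(dplyr::bind_rows(fin, fin[1, ]))
  expect_true("duplicate_row" %in% v1$violations$kind)
  # missing well row
  v2 <- validate_metadata(fin[-1, ])
  expect_true("incomplete_video" %in% v2$violations$kind)
})

test_that("fixture generation is a pure function of its seed", {
  a <- make_metadata_fixtures(seed = 10)
  b <- make_metadata_fixtures(seed = 10)
  expect_identical(a, b)
})
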