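#' Generate mutually consistent experiment-record fixtures
#'
#' Builds the full set of experiment-record tables for a small virtual
#' tracking day — `wormsorter`, `manual_metadata`, `sourceplate`,
#' `robotlog` (or `imaging2source` when the robot was not used), and the
#' recording index — together with the expected final per-(video, well)
#' metadata table constructed directly from the generator's own bookkeeping.
#' The expected table is the oracle for the provenance pipeline.
#'
#' @param seed Integer seed (controls the robot's column shuffle and the
#'   strain layout).
#' @param n_plates Imaging plates (one run each, all on one instrument).
#' @param shuffle Use the liquid-handling robot's column shuffle
#'   (`robotlog`); if `FALSE`, an identity `imaging2source` mapping.
#' @param with_compounds Include compound source-plate records.
#' @param dir If given, the CSV files are also written there.
#' @return List with `files` (named list of tibbles: `wormsorter`,
#'   `manual_metadata`, `sourceplate`, `robotlog`, `imaging2source`,
#'   `recordings`), `expected` (the expected final metadata tibble), and
#'   `column_map` (the source-to-imaging column permutation per plate).
#' @export
make_metadata_fixtures <- function(seed = 0, n_plates = 1, shuffle = TRUE,
                                   with_compounds = TRUE, dir = NULL) {
  set.seed(seed)
  plate_rows <- 8; plate_cols <- 12
  date <- "20260115"
  instrument <- "rig01"
  plates <- sprintf("IP%02d", seq_len(n_plates))
  strains <- c("N2", "CB4856", "MY16", "JU775")

  wormsorter <- purrr::map_dfr(seq_len(n_plates), function(p) {
    s <- sample(strains, 2)
    tibble::tibble(
      imaging_plate_id = plates[p],
      well_range = c("A1-D12", "E1-H12"),
      worm_strain = s,
      media_type = "NGM agar",
      bacteria_strain = "OP50"
    )
  })

  manual_metadata <- tibble::tibble(
    date_yyyymmdd = date,
    run_number = seq_len(n_plates),
    imaging_plate_id = plates,
    instrument_name = instrument,
    room_temperature_c = round(stats::runif(n_plates, 19.5, 20.5), 1),
    humidity_percent = round(stats::runif(n_plates, 40, 60))
  )

  recordings <- purrr::map_dfr(seq_len(n_plates), function(p) {
    tibble::tibble(
      video = sprintf("%s_run%02d_%s_cam%d", date, p, instrument, 1:6),
      run_number = p,
      instrument_name = instrument,
      camera_id = 1:6
    )
  })

  sourceplate <- NULL; robotlog <- NULL; imaging2source <- NULL
  column_map <- NULL
  compounds <- sprintf("compound_%02d", 1:12)
  if (with_compounds) {
    sourceplate <- purrr::map_dfr(seq_len(n_plates), function(p) {
      g <- expand.grid(col = seq_len(plate_cols), row = seq_len(plate_rows))
      tibble::tibble(
        source_plate_id = sprintf("SP%02d", p),
        source_well = paste0(LETTERS[g$row], g$col),
        compound_name = compounds[g$col],
        compound_concentration = 10 * g$col,
        concentration_units = "uM"
      )
    })
    if (shuffle) {
      column_map <- lapply(seq_len(n_plates), function(p) sample(plate_cols))
      names(column_map) <- plates
      robotlog <- purrr::map_dfr(seq_len(n_plates), function(p) {
        perm <- column_map[[p]]
        g <- expand.grid(col = seq_len(plate_cols), row = seq_len(plate_rows))
        tibble::tibble(
          source_plate_id = sprintf("SP%02d", p),
          source_well = paste0(LETTERS[g$row], g$col),
          imaging_plate_id = plates[p],
          imaging_well = paste0(LETTERS[g$row], perm[g$col])
        )
      })
    } else {
      column_map <- lapply(seq_len(n_plates), function(p) seq_len(plate_cols))
      names(column_map) <- plates
      imaging2source <- tibble::tibble(
        imaging_plate_id = plates,
        source_plate_id = sprintf("SP%02d", seq_len(n_plates))
      )
    }
  }

  # expected final table, assembled directly from the layout above
  strain_of <- function(plate, well) {
    row <- match(substr(well, 1, 1), LETTERS)
    ws <- wormsorter[wormsorter$imaging_plate_id == plate, ]
    if (row <= 4) ws$worm_strain[1] else ws$worm_strain[2]
  }
  expected <- purrr::pmap_dfr(recordings, function(video, run_number,
                                                  instrument_name, camera_id) {
    wells <- camera_well_names(4, 4, camera_id)
    plate <- plates[run_number]
    tibble::tibble(
      video = video, run_number = run_number,
      instrument_name = instrument_name, camera_id = camera_id,
      date_yyyymmdd = date,
      imaging_plate_id = plate,
      room_temperature_c =
        manual_metadata$room_temperature_c[run_number],
      humidity_percent = manual_metadata$humidity_percent[run_number],
      well_name = wells,
      worm_strain = unname(vapply(wells, strain_of, "", plate = plate)),
      media_type = "NGM agar",
      bacteria_strain = "OP50"
    )
  })
  if (with_compounds) {
    expected$source_plate_id <- sub("IP", "SP", expected$imaging_plate_id)
    inv_col <- function(plate, col) {
      # imaging column col received source column inverse-perm(col)
      match(col, column_map[[plate]])
    }
    col_img <- as.integer(substr(expected$well_name, 2, 3))
    src_col <- unname(mapply(inv_col, expected$imaging_plate_id, col_img))
    expected$source_well <- paste0(substr(expected$well_name, 1, 1), src_col)
    expected$compound_name <- compounds[src_col]
    expected$compound_concentration <- 10 * src_col
    expected$concentration_units <- "uM"
  } else {
    expected$source_plate_id <- NA_character_
    expected$source_well <- NA_character_
    expected$compound_name <- NA_character_
    expected$compound_concentration <- NA_real_
    expected$concentration_units <- NA_character_
  }
  expected$well_label_bad <- FALSE

  files <- list(
    wormsorter = wormsorter,
    manual_metadata = manual_metadata,
    sourceplate = sourceplate,
    robotlog = robotlog,
    imaging2source = imaging2source,
    recordings = recordings
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(files)) {
      if (!is.null(files[[nm]])) {
        readr::write_csv(files[[nm]], file.path(dir, paste0(nm, ".csv")))
      }
    }
  }
  list(files = files, expected = expected, column_map = column_map)
}
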