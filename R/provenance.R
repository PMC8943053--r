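#' Expand a well-range expression
#'
#' Wormsorter records describe dispensed wells compactly as inclusive
#' rectangular ranges (`"A1-B12"`: all wells with rows A..B and columns
#' 1..12), comma-separated lists, or single wells. Hyphen and en-dash are
#' both accepted.
#'
#' @param range Character scalar, e.g. `"A1-B12"` or `"A1,A3,B7"`.
#' @param plate_rows,plate_cols Plate dimensions (default 8 x 12).
#' @return Character vector of well names, row-major.
#' @export
expand_well_range <- function(range, plate_rows = 8, plate_cols = 12) {
  parts <- trimws(strsplit(range, ",", fixed = TRUE)[[1]])
  parse_well <- function(w) {
    m <- regmatches(w, regexec("^([A-Ha-h])([0-9]{1,2})$", w))[[1]]
    if (length(m) != 3) stop("malformed well name: ", w, call. = FALSE)
    r <- match(toupper(m[2]), LETTERS)
    c <- as.integer(m[3])
    if (r > plate_rows || c < 1 || c > plate_cols) {
      stop("well outside plate: ", w, call. = FALSE)
    }
    c(row = r, col = c)
  }
  out <- character(0)
  for (p in parts) {
    ends <- trimws(strsplit(p, "[-–]")[[1]])
    if (length(ends) == 1) {
      w <- parse_well(ends)
      out <- c(out, paste0(LETTERS[w["row"]], w["col"]))
    } else if (length(ends) == 2) {
      a <- parse_well(ends[1]); b <- parse_well(ends[2])
      rows <- seq(min(a["row"], b["row"]), max(a["row"], b["row"]))
      cols <- seq(min(a["col"], b["col"]), max(a["col"], b["col"]))
      g <- expand.grid(col = cols, row = rows)
      g <- g[order(g$row, g$col), ]
      out <- c(out, paste0(LETTERS[g$row], g$col))
    } else {
      stop("malformed well range: ", p, call. = FALSE)
    }
  }
  out
}

read_record_csv <- function(x) {
  out <- if (is.character(x) && length(x) == 1) {
    readr::read_csv(x, show_col_types = FALSE)
  } else {
    tibble::as_tibble(x)
  }
  # dates are identifiers (YYYYMMDD), never numbers
  if ("date_yyyymmdd" %in% names(out)) {
    out$date_yyyymmdd <- as.character(out$date_yyyymmdd)
  }
  for (col in intersect(c("run_number", "camera_id"), names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  out
}

#' Compile per-well plate metadata from experiment records
#'
#' Expands the wormsorter well ranges into individual wells of each imaging
#' plate and, when compound records are present, joins the compound contents
#' of each source-plate well through the source-to-imaging well mapping
#' (column-shuffling `robotlog` or identity `imaging2source`).
#'
#' Expected columns: `wormsorter` has `imaging_plate_id`, `well_range`,
#' `worm_strain`, `media_type`, `bacteria_strain`; `sourceplate` has
#' `source_plate_id`, `source_well`, `compound_name`,
#' `compound_concentration`, `concentration_units`; `robotlog` has
#' `source_plate_id`, `source_well`, `imaging_plate_id`, `imaging_well`;
#' `imaging2source` has `imaging_plate_id`, `source_plate_id`.
#'
#' @param wormsorter Data frame or CSV path.
#' @param sourceplate,robotlog,imaging2source Optional data frames or CSV
#'   paths.
#' @param plate_rows,plate_cols Plate dimensions.
#' @return Tibble with one row per (`imaging_plate_id`, `well_name`):
#'   strain, media, bacteria, and compound columns (NA when no compound
#'   records apply).
#' @export
compile_plate_metadata <- function(wormsorter, sourceplate = NULL,
                                   robotlog = NULL, imaging2source = NULL,
                                   plate_rows = 8, plate_cols = 12) {
  ws <- read_record_csv(wormsorter)
  need <- c("imaging_plate_id", "well_range", "worm_strain", "media_type",
            "bacteria_strain")
  if (!all(need %in% names(ws))) {
    stop("wormsorter is missing columns: ",
         paste(setdiff(need, names(ws)), collapse = ", "), call. = FALSE)
  }
  rows <- purrr::pmap_dfr(ws, function(imaging_plate_id, well_range,
                                       worm_strain, media_type,
                                       bacteria_strain, ...) {
    tibble::tibble(
      imaging_plate_id = imaging_plate_id,
      well_name = expand_well_range(well_range, plate_rows, plate_cols),
      worm_strain = worm_strain,
      media_type = media_type,
      bacteria_strain = bacteria_strain
    )
  })
  dup <- rows |>
    dplyr::count(.data$imaging_plate_id, .data$well_name) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("overlapping well ranges for plate(s): ",
         paste(unique(dup$imaging_plate_id), collapse = ", "), call. = FALSE)
  }

  compound_cols <- tibble::tibble(
    source_plate_id = NA_character_, source_well = NA_character_,
    compound_name = NA_character_, compound_concentration = NA_real_,
    concentration_units = NA_character_
  )
  meta <- dplyr::bind_cols(rows, compound_cols[rep(1, nrow(rows)), ])

  map <- NULL
  if (!is.null(robotlog)) {
    map <- read_record_csv(robotlog)
  } else if (!is.null(imaging2source)) {
    i2s <- read_record_csv(imaging2source)
    # identity well mapping: every dispensed well of the imaging plate comes
    # from the same-named well of its source plate
    map <- rows |>
      dplyr::inner_join(i2s, by = "imaging_plate_id") |>
      dplyr::transmute(
        source_plate_id = .data$source_plate_id,
        source_well = .data$well_name,
        imaging_plate_id = .data$imaging_plate_id,
        imaging_well = .data$well_name
      )
  }
  if (!is.null(map) && !is.null(sourceplate)) {
    sp <- read_record_csv(sourceplate)
    key_meta <- paste(meta$imaging_plate_id, meta$well_name)
    key_map <- paste(map$imaging_plate_id, map$imaging_well)
    orphan <- setdiff(key_map, key_meta)
    if (length(orphan) > 0) {
      stop("robotlog references imaging wells absent from wormsorter: ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
    joined <- map |>
      dplyr::left_join(sp, by = c("source_plate_id", "source_well"))
    i <- match(key_map, key_meta)
    meta$source_plate_id[i] <- joined$source_plate_id
    meta$source_well[i] <- joined$source_well
    meta$compound_name[i] <- joined$compound_name
    meta$compound_concentration[i] <- joined$compound_concentration
    meta$concentration_units[i] <- joined$concentration_units
  }
  tibble::as_tibble(meta)
}

#' Compile the final per-(video, well) metadata table
#'
#' Joins the per-plate well metadata with the manual run log and the
#' recording index: each (run, instrument) pair identifies one imaging
#' plate; each video belongs to one (run, instrument, camera) and
#' contributes one row per well of that camera's block.
#'
#' Expected columns: `manual_metadata` has `date_yyyymmdd`, `run_number`,
#' `imaging_plate_id`, `instrument_name` plus any environmental columns;
#' `recordings` has `video`, `run_number`, `instrument_name`, `camera_id`.
#'
#' @param plate_metadata Output of [compile_plate_metadata()].
#' @param manual_metadata Data frame or CSV path of the manual run log.
#' @param recordings Data frame: the recording index (one row per video).
#' @param grid_rows,grid_cols Well block dimensions seen by one camera.
#' @param bad_wells Optional data frame (`video`, `well_name`) of
#'   manually flagged bad wells.
#' @return Tibble with one row per (video, well in the video's camera
#'   block), carrying all plate metadata plus run/instrument/camera/date
#'   fields and a `well_label_bad` flag.
#' @export
compile_final_metadata <- function(plate_metadata, manual_metadata,
                                   recordings, grid_rows = 4, grid_cols = 4,
                                   bad_wells = NULL) {
  mm <- read_record_csv(manual_metadata)
  rec <- read_record_csv(recordings)
  dup <- mm |>
    dplyr::count(.data$run_number, .data$instrument_name) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (run, instrument) rows in manual metadata", call. = FALSE)
  }
  rec2 <- rec |>
    dplyr::left_join(mm, by = c("run_number", "instrument_name"))
  if (anyNA(rec2$imaging_plate_id)) {
    bad <- rec2$video[is.na(rec2$imaging_plate_id)]
    stop("video(s) with no manual-metadata row: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- rec2 |>
    dplyr::mutate(
      well_name = purrr::map(.data$camera_id,
                             ~ camera_well_names(grid_rows, grid_cols, .x))
    ) |>
    tidyr::unnest("well_name") |>
    dplyr::inner_join(plate_metadata, by = c("imaging_plate_id", "well_name"))
  n_expected <- nrow(rec) * grid_rows * grid_cols
  if (nrow(out) != n_expected) {
    stop("plate metadata does not cover every well of every video", call. = FALSE)
  }
  out$well_label_bad <- FALSE
  if (!is.null(bad_wells)) {
    bw <- read_record_csv(bad_wells)
    key <- paste(out$video, out$well_name)
    out$well_label_bad <- key %in% paste(bw$video, bw$well_name)
  }
  tibble::as_tibble(out)
}

#' Validate a final metadata table
#'
#' Machine-readable consistency report: uniqueness of (video, well), a
#' complete well block per video, and absence of missing key fields.
#'
#' @param final Output of [compile_final_metadata()].
#' @param wells_per_video Expected wells per video (16 for the default
#'   camera geometry).
#' @return List with `n_violations` and `violations` (tibble of `kind`,
#'   `detail`).
#' @export
validate_metadata <- function(final, wells_per_video = 16) {
  v <- list()
  dup <- final |>
    dplyr::count(.data$video, .data$well_name) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    v[[length(v) + 1]] <- tibble::tibble(
      kind = "duplicate_row",
      detail = paste(dup$video, dup$well_name)
    )
  }
  cnt <- final |> dplyr::count(.data$video)
  bad <- cnt[cnt$n != wells_per_video, ]
  if (nrow(bad) > 0) {
    v[[length(v) + 1]] <- tibble::tibble(
      kind = "incomplete_video",
      detail = sprintf("%s has %d wells (expected %d)",
                       bad$video, bad$n, wells_per_video)
    )
  }
  for (col in c("imaging_plate_id", "worm_strain", "well_name")) {
    if (col %in% names(final) && anyNA(final[[col]])) {
      v[[length(v) + 1]] <- tibble::tibble(
        kind = "missing_value", detail = col
      )
    }
  }
  violations <- if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(kind = character(), detail = character())
  list(n_violations = nrow(violations), violations = violations)
}
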