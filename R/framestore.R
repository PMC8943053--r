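#' Write a frame store to a directory
#'
#' Writes frames as 8-bit grayscale PNGs (`frame_000000.png`, ...), the
#' per-frame index as `index.csv` (columns `frame_number`, `timestamp_s`)
#' and the acquisition metadata as `metadata.yaml`.
#'
#' @param store A `frame_store` (see [simulate_session()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_framestore <- function(store, dir) {
  stopifnot(inherits(store, "frame_store"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(store$frames)) {
    for (i in seq_along(store$frames)) {
      m <- frame_to_num(store$frames[[i]]) / 255
      png::writePNG(m, file.path(dir, sprintf("frame_%06d.png",
                                              store$index$frame_number[i])))
    }
  }
  readr::write_csv(store$index, file.path(dir, "index.csv"))
  yaml::write_yaml(store$metadata, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Read a frame store from a directory
#'
#' Inverse of [write_framestore()]. Frames are returned as raw 8-bit
#' matrices.
#'
#' @param dir Directory written by [write_framestore()].
#' @return A `frame_store`.
#' @export
read_framestore <- function(dir) {
  idx <- readr::read_csv(file.path(dir, "index.csv"), show_col_types = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  files <- file.path(dir, sprintf("frame_%06d.png", idx$frame_number))
  frames <- NULL
  if (all(file.exists(files))) {
    frames <- lapply(files, function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3) m <- m[, , 1]
      num_to_frame(m * 255)
    })
  }
  structure(
    list(frames = frames, index = tibble::as_tibble(idx), metadata = meta),
    class = "frame_store"
  )
}

#' Fetch one frame as a numeric matrix
#'
#' @param store A `frame_store`.
#' @param frame_number Frame number as recorded in the index.
#' @return Numeric matrix with values in 0..255.
#' @export
get_frame <- function(store, frame_number) {
  i <- match(frame_number, store$index$frame_number)
  if (is.na(i)) stop("frame_number not in store index", call. = FALSE)
  frame_to_num(store$frames[[i]])
}
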