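#' Camera-array design arithmetic
#'
#' Back-of-the-envelope checks for a megapixel camera-array tracker: the
#' pixel budget needed to cover a plate at a target resolution, the raw data
#' rate of the array, the resolution achieved by a given pixel size, and the
#' number of wells recorded simultaneously by several identical units.
#' These are pure arithmetic, exposed so design assumptions are testable.
#'
#' @name design_arithmetic
NULL

#' @describeIn design_arithmetic Pixels needed to image a field of
#'   `field_mm = c(width, height)` millimetres at `px_per_mm`. Returns a
#'   tibble with the pixel dimensions, the total in megapixels, and the
#'   aspect ratio.
#' @param field_mm Numeric length-2, field of view in mm (width, height).
#'   The default covers the well area of a 96-well plate with a 3:2 aspect.
#' @param px_per_mm Target resolution in pixels per mm.
#' @export
design_pixel_budget <- function(field_mm = c(108, 72), px_per_mm = 75) {
  px <- field_mm * px_per_mm
  tibble::tibble(
    width_px = px[1], height_px = px[2],
    megapixels = px[1] * px[2] / 1e6,
    aspect = px[1] / px[2]
  )
}

#' @describeIn design_arithmetic Raw (uncompressed) data produced by the
#'   array, in terabytes (1 TB = 1e12 bytes) over `hours` of recording.
#' @param megapixels_per_camera Sensor resolution of one camera, in Mpx.
#' @param fps Frame rate in frames/s.
#' @param n_cameras Cameras in the array.
#' @param bytes_per_px Bytes per pixel (1 for 8-bit grayscale).
#' @param hours Recording duration in hours.
#' @export
design_data_rate_tb <- function(megapixels_per_camera = 12, fps = 25,
                                n_cameras = 6, bytes_per_px = 1, hours = 1) {
  megapixels_per_camera * 1e6 * bytes_per_px * fps * n_cameras * 3600 * hours / 1e12
}

#' @describeIn design_arithmetic Resolution in px/mm achieved by a pixel
#'   size of `um_per_px` micrometres.
#' @param um_per_px Pixel size in micrometres.
#' @export
design_resolution_px_per_mm <- function(um_per_px = 12.4) {
  1000 / um_per_px
}

#' @describeIn design_arithmetic Wells recorded simultaneously by
#'   `n_units` identical camera-array units, each imaging one
#'   `wells_per_plate` plate.
#' @param n_units Number of identical imaging units.
#' @param wells_per_plate Wells per plate.
#' @export
design_simultaneous_wells <- function(n_units = 5, wells_per_plate = 96) {
  n_units * wells_per_plate
}
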