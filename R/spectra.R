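# Containers for IMS data: mass spectra, pixel datasets and ROIs.

#' Construct a mass spectrum
#'
#' @param mz Strictly increasing numeric vector of m/z values (Da).
#' @param intensity Non-negative numeric vector, same length as `mz`.
#' @return Object of class `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (length(mz) && any(diff(mz) <= 0))
    stop("mz must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("Mass spectrum: %d points, m/z %.2f-%.2f, TIC %.3g\n",
              length(x$mz), min(x$mz), max(x$mz), sum(x$intensity)))
  invisible(x)
}

#' Construct an IMS dataset
#'
#' Continuous-mode container: one shared m/z axis, one intensity row per
#' pixel. Pixel coordinates are 0-based, `x` = column, `y` = row, origin at
#' the top-left (imzML's 1-based coordinates are converted on read).
#'
#' @param coords Data frame with integer columns `x`, `y`; rows must be
#'   unique and align with the rows of `intensities`.
#' @param mz Shared m/z axis (strictly increasing).
#' @param intensities Numeric matrix, `nrow(coords)` x `length(mz)`.
#' @param pixel_pitch Laser step distance in micrometers (default 70).
#' @param metadata Free-form provenance list.
#' @return Object of class `ims_dataset`.
#' @export
ims_dataset <- function(coords, mz, intensities, pixel_pitch = 70,
                        metadata = list()) {
  coords <- as.data.frame(coords)
  stopifnot(all(c("x", "y") %in% names(coords)))
  coords$x <- as.integer(coords$x); coords$y <- as.integer(coords$y)
  if (anyDuplicated(coords[c("x", "y")]))
    stop("pixel coordinates must be unique")
  if (!is.matrix(intensities))
    intensities <- matrix(intensities, nrow = nrow(coords), byrow = TRUE)
  if (nrow(intensities) != nrow(coords) || ncol(intensities) != length(mz))
    stop("intensities must be nrow(coords) x length(mz)")
  if (any(diff(mz) <= 0)) stop("mz axis must be strictly increasing")
  if (pixel_pitch <= 0) stop("pixel_pitch must be > 0")
  structure(list(coords = coords[, c("x", "y")], mz = as.numeric(mz),
                 intensities = intensities, pixel_pitch = pixel_pitch,
                 metadata = metadata),
            class = "ims_dataset")
}

#' @export
print.ims_dataset <- function(x, ...) {
  cat(sprintf(
    "IMS dataset: %d pixels, %d m/z bins (%.2f-%.2f), pitch %g um\n",
    nrow(x$coords), length(x$mz), min(x$mz), max(x$mz), x$pixel_pitch))
  invisible(x)
}

#' Construct a region-of-interest record
#'
#' @param pixels Integer indices (1-based rows into a dataset's pixel list).
#' @param region Anatomical region label.
#' @param hemisphere `"left"` or `"right"`.
#' @param section_id Section label.
#' @param animal_id Animal label.
#' @param dataset_id Identifier of the dataset the indices refer to.
#' @return Object of class `ims_roi`.
#' @export
ims_roi <- function(pixels, region, hemisphere, section_id, animal_id,
                    dataset_id = NA_character_) {
  pixels <- as.integer(pixels)
  if (!length(pixels)) stop("ROI must contain at least one pixel")
  for (f in c(region, hemisphere, section_id, animal_id))
    if (!is.character(f) || !nzchar(f)) stop("ROI provenance fields must be non-empty strings")
  if (!hemisphere %in% c("left", "right"))
    stop("hemisphere must be 'left' or 'right'")
  structure(list(pixels = pixels, region = region, hemisphere = hemisphere,
                 section_id = section_id, animal_id = animal_id,
                 dataset_id = dataset_id),
            class = "ims_roi")
}

roi_key <- function(roi) {
  paste(roi$animal_id, roi$section_id, roi$hemisphere, roi$region, sep = "|")
}
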