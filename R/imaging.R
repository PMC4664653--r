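# Per-species ion images and two-channel composites.

#' Render an ion image for one species
#'
#' Quantifies the target's baseline-corrected highest-peak AUC in every
#' pixel and arranges the values on the pixel grid. Pixels where no peak
#' clears the detection floor are set to 0 (image context) rather than
#' excluded; grid positions with no acquired pixel are `NA` (off-tissue).
#' Values are normalized to the image maximum, so images are comparable
#' within, never across, images.
#'
#' @param dataset An [ims_dataset()].
#' @param target A [species_target()].
#' @param flank_width,floor_k,baseline_method As in [roi_ratio()].
#' @return Object of class `ion_image`: list with `values` (normalized
#'   grid, rows = y), `raw`, `species`, `max_raw`, `pixel_pitch`.
#' @export
render_ion_image <- function(dataset, target, flank_width = 1.0,
                             floor_k = 3, baseline_method = "linear") {
  stopifnot(inherits(dataset, "ims_dataset"),
            inherits(target, "species_target"))
  n_px <- nrow(dataset$coords)
  if (!n_px) stop("empty dataset")
  auc <- vapply(seq_len(n_px), function(i) {
    spec <- mass_spectrum(dataset$mz, dataset$intensities[i, ])
    q <- .quantify_target(spec, target, flank_width, floor_k,
                          baseline_method)
    if (q$found) q$auc else 0
  }, numeric(1))
  nr <- max(dataset$coords$y) + 1L
  nc <- max(dataset$coords$x) + 1L
  raw <- matrix(NA_real_, nr, nc)
  raw[cbind(dataset$coords$y + 1L, dataset$coords$x + 1L)] <- auc
  mx <- max(raw, na.rm = TRUE)
  if (mx <= 0) {
    warning("all-zero ion image for ", target$name, "; not normalized")
    values <- raw
  } else {
    values <- raw / mx
  }
  structure(list(values = values, raw = raw, species = target$name,
                 max_raw = mx, pixel_pitch = dataset$pixel_pitch),
            class = "ion_image")
}

#' Two-channel composite of ion images
#'
#' Overlays two normalized ion images as green and red channels (equal
#' channel values render yellow). Off-tissue positions are black.
#'
#' @param green,red [render_ion_image()] results on the same grid.
#' @return Object of class `ims_composite`: an `nrow x ncol x 3` RGB array
#'   in `[0, 1]` with `pixel_pitch` attribute.
#' @export
composite_image <- function(green, red) {
  stopifnot(inherits(green, "ion_image"), inherits(red, "ion_image"))
  if (!identical(dim(green$values), dim(red$values)))
    stop("ion images are on different grids")
  g <- green$values; r <- red$values
  g[is.na(g)] <- 0; r[is.na(r)] <- 0
  img <- array(0, dim = c(nrow(g), ncol(g), 3L))
  img[, , 1] <- r
  img[, , 2] <- g
  structure(img, class = "ims_composite", pixel_pitch = green$pixel_pitch,
            channels = c(red = red$species, green = green$species))
}

#' Write a composite image as PNG with a scale bar
#'
#' @param composite An `ims_composite` from [composite_image()].
#' @param path Output PNG path.
#' @param scale_bar_um Scale-bar length in micrometers (drawn white,
#'   bottom-left), derived from the pixel pitch; 0 suppresses it.
#' @return Invisibly, `path`.
#' @export
write_composite_png <- function(composite, path, scale_bar_um = 500) {
  stopifnot(inherits(composite, "ims_composite"))
  img <- unclass(composite)
  if (scale_bar_um > 0) {
    pitch <- attr(composite, "pixel_pitch")
    len <- max(1L, round(scale_bar_um / pitch))
    nr <- dim(img)[1]; nc <- dim(img)[2]
    rows <- max(1L, nr - 1L):nr
    cols <- 1:min(len, nc)
    img[rows, cols, ] <- 1
  }
  png::writePNG(img, target = path)
  invisible(path)
}
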