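# ROI mean spectra, per-animal averaging with the minimum-measurement
# exclusion rule, and per-region mean +/- SEM summaries.

#' Mean spectrum over an ROI
#'
#' Unweighted per-bin mean of the member pixels' intensities on the shared
#' dataset axis.
#'
#' @param dataset An [ims_dataset()].
#' @param roi An [ims_roi()] with valid pixel indices into `dataset`.
#' @return A [mass_spectrum()].
#' @export
roi_mean_spectrum <- function(dataset, roi) {
  stopifnot(inherits(dataset, "ims_dataset"), inherits(roi, "ims_roi"))
  if (!length(roi$pixels)) stop("empty ROI")
  if (any(roi$pixels < 1L | roi$pixels > nrow(dataset$coords)))
    stop("ROI pixel indices outside dataset")
  mass_spectrum(dataset$mz,
                colMeans(dataset$intensities[roi$pixels, , drop = FALSE]))
}

#' Per-animal, per-region mean ratios with exclusion rule
#'
#' Groups valid ROI ratio records by (animal, region) and averages them.
#' Groups with fewer than `min_measurements` valid measurements are dropped
#' (with a message), mirroring the rule that an animal's region with fewer
#' than two usable measurements does not enter the analysis.
#'
#' @param records Data frame from [quantify_rois()].
#' @param min_measurements Minimum valid measurements per animal-region
#'   (default 2).
#' @return Data frame: `animal_id`, `region`, `mean_ratio`,
#'   `n_measurements`.
#' @export
animal_averages <- function(records, min_measurements = 2L) {
  stopifnot(is.data.frame(records),
            all(c("animal_id", "region", "ratio", "valid") %in%
                  names(records)))
  ok <- records[records$valid & is.finite(records$ratio), , drop = FALSE]
  if (!nrow(ok))
    return(data.frame(animal_id = character(), region = character(),
                      mean_ratio = numeric(), n_measurements = integer()))
  key <- interaction(ok$animal_id, ok$region, drop = TRUE)
  out <- do.call(rbind, lapply(split(ok, key), function(g)
    data.frame(animal_id = g$animal_id[1], region = g$region[1],
               mean_ratio = mean(g$ratio), n_measurements = nrow(g),
               stringsAsFactors = FALSE)))
  drop <- out$n_measurements < min_measurements
  if (any(drop))
    message("excluding ", sum(drop), " animal-region group(s) with fewer ",
            "than ", min_measurements, " measurements: ",
            paste(out$animal_id[drop], out$region[drop], sep = "/",
                  collapse = ", "))
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$region, out$animal_id), , drop = FALSE]
}

#' Per-region summaries over per-animal means
#'
#' The animal is the unit of analysis: the summary mean and SEM are taken
#' over per-animal mean ratios, with SEM = sample sd / sqrt(n_animals). A
#' single-animal region gets SEM 0 by convention (flagged by `n_animals`).
#'
#' @param means Data frame from [animal_averages()].
#' @return Data frame: `region`, `mean`, `sem`, `n_animals`.
#' @export
region_summaries <- function(means) {
  stopifnot(is.data.frame(means),
            all(c("region", "mean_ratio") %in% names(means)))
  out <- do.call(rbind, lapply(split(means, means$region), function(g) {
    n <- nrow(g)
    data.frame(region = g$region[1], mean = mean(g$mean_ratio),
               sem = if (n > 1L) stats::sd(g$mean_ratio) / sqrt(n) else 0,
               n_animals = n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$region), , drop = FALSE]
}
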