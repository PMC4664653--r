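# Targeted highest-peak location, AUC integration, and per-ROI
# d18:1/d20:1 ratios.

#' Locate the highest peak near a species' predicted m/z
#'
#' Finds the maximum-intensity local maximum within `predicted_mz +/-
#' search_halfwidth` of a baseline-corrected spectrum. Ties are broken
#' toward the candidate closest to the predicted m/z, then toward lower m/z.
#' The apex must exceed a detection floor of `floor_k` times the MAD of the
#' corrected flanking windows; below it (or with no local maximum) the peak
#' is reported as not found rather than quantifying noise.
#'
#' @param spectrum Baseline-corrected [mass_spectrum()] from
#'   [remove_local_baseline()] (window plus flanks).
#' @param target A [species_target()].
#' @param flank_width Flank width (Da) used during baseline removal; defines
#'   the noise-floor region.
#' @param floor_k Detection-floor multiplier (default 3).
#' @return List with `mz`, `intensity`, `found`, and the search `window`.
#' @export
find_highest_peak <- function(spectrum, target, flank_width = 1.0,
                              floor_k = 3) {
  stopifnot(inherits(spectrum, "mass_spectrum"),
            inherits(target, "species_target"))
  lo <- target$predicted_mz - target$search_halfwidth
  hi <- target$predicted_mz + target$search_halfwidth
  window <- c(lo, hi)
  mz <- spectrum$mz; y <- spectrum$intensity
  inw <- which(mz >= lo & mz <= hi)
  not_found <- list(mz = NA_real_, intensity = NA_real_, found = FALSE,
                    window = window)
  if (length(inw) < 3L) return(not_found)

  win <- .target_window(target)
  flank <- y[mz < win[1] | mz > win[2]]
  floor <- if (length(flank)) floor_k * stats::mad(flank) else 0

  # local maxima (plateau points count; window-edge points do not)
  cand <- inw[inw > 1L & inw < length(mz)]
  cand <- cand[y[cand] >= y[cand - 1L] & y[cand] >= y[cand + 1L]]
  cand <- cand[y[cand] > max(floor, 0)]
  if (!length(cand)) return(not_found)

  best <- cand[y[cand] == max(y[cand])]
  if (length(best) > 1L) {
    d <- abs(mz[best] - target$predicted_mz)
    best <- best[d == min(d)]
    best <- best[which.min(mz[best])]
  }
  list(mz = mz[best], intensity = y[best], found = TRUE, window = window)
}

#' Integrate the area under a peak
#'
#' Trapezoidal integral of the baseline-corrected intensities over
#' `apex_mz +/- integration_halfwidth`. The default half-width (0.4 Da)
#' stays within one isotope spacing so only the targeted highest peak is
#' integrated.
#'
#' @param spectrum Baseline-corrected [mass_spectrum()].
#' @param apex_mz Apex location from [find_highest_peak()].
#' @param target A [species_target()].
#' @return AUC (intensity x Da), >= 0.
#' @export
integrate_auc <- function(spectrum, apex_mz, target) {
  stopifnot(inherits(spectrum, "mass_spectrum"), is.finite(apex_mz))
  lo <- apex_mz - target$integration_halfwidth
  hi <- apex_mz + target$integration_halfwidth
  if (lo < min(spectrum$mz) || hi > max(spectrum$mz))
    stop(sprintf("integration bounds [%.2f, %.2f] exceed corrected window",
                 lo, hi))
  idx <- which(spectrum$mz >= lo & spectrum$mz <= hi)
  if (length(idx) < 2L) return(0)
  mz <- spectrum$mz[idx]; y <- spectrum$intensity[idx]
  sum(diff(mz) * (y[-length(y)] + y[-1]) / 2)
}

# quantify one target on an (uncorrected) spectrum: baseline removal,
# apex search, AUC
.quantify_target <- function(spectrum, target, flank_width = 1.0,
                             floor_k = 3, baseline_method = "linear") {
  corrected <- remove_local_baseline(spectrum, target,
                                     flank_width = flank_width,
                                     method = baseline_method)
  apex <- find_highest_peak(corrected, target, flank_width = flank_width,
                            floor_k = floor_k)
  if (!apex$found)
    return(list(species = target$name, apex_mz = NA_real_,
                apex_intensity = NA_real_, auc = NA_real_, found = FALSE))
  list(species = target$name, apex_mz = apex$mz,
       apex_intensity = apex$intensity,
       auc = integrate_auc(corrected, apex$mz, target), found = TRUE)
}

#' Quantify the species ratio for one ROI
#'
#' Computes the ROI mean spectrum, removes the local baseline per target,
#' integrates each species' highest peak and forms the ratio
#' `AUC(first target) / AUC(second target)` (d18:1/d20:1 with the default
#' targets). Records where either peak is missing, or the denominator AUC is
#' not positive, are flagged invalid with a reason instead of erroring.
#'
#' @param dataset An [ims_dataset()].
#' @param roi An [ims_roi()].
#' @param targets List of two [species_target()]s (numerator first).
#' @param flank_width,floor_k,baseline_method Passed to the baseline and
#'   peak-finding steps.
#' @return One-row data frame: provenance fields, per-species apex/AUC,
#'   `ratio`, `valid`, `reason`.
#' @export
roi_ratio <- function(dataset, roi, targets = gm1_species_targets(),
                      flank_width = 1.0, floor_k = 3,
                      baseline_method = "linear") {
  stopifnot(inherits(roi, "ims_roi"), length(targets) == 2L)
  spec <- roi_mean_spectrum(dataset, roi)
  q1 <- .quantify_target(spec, targets[[1]], flank_width, floor_k,
                         baseline_method)
  q2 <- .quantify_target(spec, targets[[2]], flank_width, floor_k,
                         baseline_method)
  valid <- TRUE; reason <- ""
  if (!q1$found || !q2$found) {
    valid <- FALSE
    reason <- paste0("peak not found: ",
                     paste(c(q1$species[!q1$found], q2$species[!q2$found]),
                           collapse = ", "))
  } else if (q2$auc <= 0) {
    valid <- FALSE
    reason <- paste0("non-positive denominator AUC (", q2$species, ")")
  }
  data.frame(animal_id = roi$animal_id, section_id = roi$section_id,
             hemisphere = roi$hemisphere, region = roi$region,
             dataset_id = roi$dataset_id,
             apex_mz_1 = q1$apex_mz, auc_1 = q1$auc,
             apex_mz_2 = q2$apex_mz, auc_2 = q2$auc,
             ratio = if (valid) q1$auc / q2$auc else NA_real_,
             valid = valid, reason = reason,
             stringsAsFactors = FALSE)
}

#' Quantify all ROIs of a study
#'
#' @param datasets Named list of [ims_dataset()]s (names are dataset ids).
#' @param rois List of [ims_roi()]s referring to those datasets.
#' @inheritParams roi_ratio
#' @return Tidy data frame, one row per ROI (see [roi_ratio()]).
#' @export
quantify_rois <- function(datasets, rois, targets = gm1_species_targets(),
                          flank_width = 1.0, floor_k = 3,
                          baseline_method = "linear") {
  rows <- lapply(rois, function(roi) {
    ds <- datasets[[roi$dataset_id]]
    if (is.null(ds)) stop("ROI refers to unknown dataset: ", roi$dataset_id)
    roi_ratio(ds, roi, targets, flank_width, floor_k, baseline_method)
  })
  do.call(rbind, rows)
}
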