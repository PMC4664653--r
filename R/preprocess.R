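# Local baseline removal around a targeted peak cluster.

# analysis window spans the apex search window plus the integration window,
# so every admissible integration range lies inside the corrected region
.target_window <- function(target) {
  hw <- target$search_halfwidth + target$integration_halfwidth
  c(target$predicted_mz - hw, target$predicted_mz + hw)
}

#' Remove the local baseline around a targeted peak
#'
#' Estimates the baseline under a species' peak cluster and subtracts it,
#' returning the corrected spectrum restricted to the analysis window plus
#' its flanks. The default estimator draws a straight line through the
#' minimum-intensity point of each flanking sub-window (just outside the
#' analysis window): it is deterministic, parameter-light, and removes
#' constant and linear baselines exactly. A morphological top-hat (opening)
#' estimator is available for sensitivity analysis. Negative residuals are
#' clipped to 0; the input spectrum is left untouched.
#'
#' @param spectrum A [mass_spectrum()] whose range covers the target window
#'   plus flanks.
#' @param target A [species_target()].
#' @param flank_width Width (Da) of each flanking sub-window (default 1.0).
#' @param method `"linear"` (flank-minima interpolation) or `"tophat"`
#'   (morphological opening with a `2 * flank_width` structuring element).
#' @return Corrected [mass_spectrum()] restricted to the window and flanks.
#' @export
remove_local_baseline <- function(spectrum, target, flank_width = 1.0,
                                  method = c("linear", "tophat")) {
  stopifnot(inherits(spectrum, "mass_spectrum"),
            inherits(target, "species_target"), flank_width > 0)
  method <- match.arg(method)
  win <- .target_window(target)
  lo <- win[1] - flank_width; hi <- win[2] + flank_width
  if (win[1] < min(spectrum$mz) || win[2] > max(spectrum$mz))
    stop(sprintf(
      "target window [%.2f, %.2f] outside spectrum range [%.2f, %.2f]",
      win[1], win[2], min(spectrum$mz), max(spectrum$mz)))
  keep <- which(spectrum$mz >= lo & spectrum$mz <= hi)
  mz <- spectrum$mz[keep]; y <- spectrum$intensity[keep]

  if (method == "linear") {
    left <- which(mz < win[1]); right <- which(mz > win[2])
    if (!length(left) || !length(right))
      stop("flanking windows contain no data points")
    il <- left[which.min(y[left])]; ir <- right[which.min(y[right])]
    slope <- (y[ir] - y[il]) / (mz[ir] - mz[il])
    base <- y[il] + slope * (mz - mz[il])
  } else {
    half <- max(1L, round(flank_width / stats::median(diff(mz))))
    n <- length(y)
    roll <- function(v, f) {
      vapply(seq_len(n), function(i)
        f(v[max(1L, i - half):min(n, i + half)]), numeric(1))
    }
    base <- roll(roll(y, min), max)  # morphological opening
  }
  mass_spectrum(mz, pmax(y - base, 0))
}
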