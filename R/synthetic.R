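# Seeded synthetic IMS studies: multi-region brain phantoms carrying
# region-specific GM1d18:1/GM1d20:1 abundance ratios, with isotope-resolved
# peaks, additive baseline, per-pixel multiplicative gain and additive noise.

#' Construct a region map (phantom grid)
#'
#' @param grid Character matrix of region labels; `NA` marks off-tissue.
#' @param pixel_pitch Laser step distance in micrometers (default 70).
#' @return Object of class `region_map`.
#' @export
region_map <- function(grid, pixel_pitch = 70) {
  if (!is.matrix(grid)) stop("grid must be a matrix of labels")
  if (all(is.na(grid))) stop("region map needs at least one on-tissue pixel")
  if (pixel_pitch <= 0) stop("pixel_pitch must be > 0")
  structure(list(grid = grid, pixel_pitch = pixel_pitch,
                 regions = sort(unique(grid[!is.na(grid)]))),
            class = "region_map")
}

#' Build a named phantom layout
#'
#' Deterministic label grids for one hemisphere; [simulate_study()] mirrors
#' the map to produce the left/right tissue grid.
#'
#' Layouts: `"single"` (one region), `"pair"` (two horizontal blocks, e.g.
#' two white-matter tracts), `"cortex3"` (three equal-depth horizontal bands:
#' superficial, intermediate, deep), `"hippocampus6"` (six vertical strips
#' emulating small hippocampal sampling fields).
#'
#' @param layout Layout name.
#' @param dims `c(nrow, ncol)`, both >= 8.
#' @param labels Optional region labels overriding the layout defaults.
#' @param pixel_pitch Micrometers per pixel.
#' @return A [region_map()].
#' @export
build_phantom <- function(layout = c("single", "pair", "cortex3",
                                     "hippocampus6"),
                          dims = c(24, 24), labels = NULL, pixel_pitch = 70) {
  layout <- match.arg(layout)
  dims <- as.integer(dims)
  if (length(dims) != 2L || any(dims < 8L))
    stop("dims must be two integers >= 8")
  nr <- dims[1]; nc <- dims[2]
  default_labels <- switch(layout,
    single = "region1",
    pair = c("regionA", "regionB"),
    cortex3 = c("superficial", "intermediate", "deep"),
    hippocampus6 = c("DG_gc", "DG_ml", "CA1_pc", "CA1_rad", "CA3_pc",
                     "CA3_rad"))
  if (is.null(labels)) labels <- default_labels
  if (length(labels) != length(default_labels))
    stop("layout '", layout, "' needs ", length(default_labels), " labels")
  grid <- switch(layout,
    single = matrix(labels, nr, nc),
    pair = matrix(labels[1 + (seq_len(nr) > nr / 2)], nr, nc),
    cortex3 = matrix(labels[pmin(3L, 1L + (seq_len(nr) - 1L) %/%
                                   (nr %/% 3L))], nr, nc),
    hippocampus6 = matrix(labels[pmin(6L, 1L + (rep(seq_len(nc),
                                                    each = nr) - 1L) %/%
                                        (nc %/% 6L))], nr, nc))
  region_map(grid, pixel_pitch)
}

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic-data generator: the m/z
#' axis, per-region total GM1 signal and true d18:1/d20:1 highest-peak ratio,
#' baseline model, per-pixel gain and noise, between-animal variability and
#' the study design (animals, sections, hemispheres).
#'
#' The two species' abundances in a region are parameterized from the
#' region's `ratio` so that the expected highest-peak AUC ratio (the
#' measurand) equals `ratio` exactly: with monoisotopic envelope fractions
#' f18, f20 and rho = ratio * f20 / f18, the d18:1 abundance is
#' `total * rho / (1 + rho)` and the d20:1 abundance `total / (1 + rho)`.
#'
#' @param regions Named list; each element a list with `total` (summed
#'   species abundance, arbitrary units) and `ratio` (true d18:1/d20:1
#'   highest-peak AUC ratio, > 0).
#' @param mz_range Acquired m/z range `(low, high)` in Da.
#' @param mz_bin Axis bin width (Da); continuous-mode shared axis.
#' @param peak_sigma Gaussian mass-spectral peak sd (Da).
#' @param baseline List with `constant`, `slope` (per Da, relative to the
#'   axis start) and a broad Gaussian bump (`bump_amplitude`, `bump_center`,
#'   `bump_sd`).
#' @param gain_sdlog Log-sd of the per-pixel lognormal gain (median 1).
#' @param noise_sd Additive zero-mean Gaussian noise sd; intensities are
#'   clipped at 0.
#' @param animal_cv Coefficient of variation of the lognormal per-animal
#'   multiplier on each region's true ratio (mean 1); emulates biological
#'   between-animal spread.
#' @param n_animals,sections_per_animal,hemispheres Study design.
#' @param drop_roi_rate Probability of dropping any single ROI from the ROI
#'   set (exercises the minimum-measurement exclusion rule downstream).
#' @param seed Master RNG seed; all child streams derive from it.
#' @param targets Species targets (default [gm1_species_targets()]); the
#'   first is the ratio numerator.
#' @param envelope_peaks Isotope peaks simulated per species.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(regions,
                       mz_range = c(1000, 2000), mz_bin = 0.02,
                       peak_sigma = 0.15,
                       baseline = list(constant = 2, slope = -0.001,
                                       bump_amplitude = 3,
                                       bump_center = 1520, bump_sd = 60),
                       gain_sdlog = 0.25, noise_sd = 0.5,
                       animal_cv = 0.10,
                       n_animals = 1L, sections_per_animal = 2L,
                       hemispheres = c("left", "right"),
                       drop_roi_rate = 0, seed = 1L,
                       targets = gm1_species_targets(),
                       envelope_peaks = 5L) {
  if (!is.list(regions) || is.null(names(regions)) ||
      any(!nzchar(names(regions))))
    stop("regions must be a named list")
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (is.null(r$total) || is.null(r$ratio) || r$total <= 0 || r$ratio <= 0)
      stop("region '", nm, "' needs positive total and ratio")
  }
  stopifnot(length(mz_range) == 2L, mz_range[1] < mz_range[2],
            mz_bin > 0, peak_sigma > 0, gain_sdlog >= 0, noise_sd >= 0,
            animal_cv >= 0, n_animals >= 1L, sections_per_animal >= 1L,
            drop_roi_rate >= 0, drop_roi_rate <= 1,
            length(targets) == 2L)
  bl_defaults <- list(constant = 2, slope = -0.001, bump_amplitude = 3,
                      bump_center = 1520, bump_sd = 60)
  baseline <- utils::modifyList(bl_defaults, baseline)
  envelopes <- lapply(targets, function(t)
    isotope_envelope(t$formula, max_peaks = envelope_peaks,
                     normalize = "sum"))
  for (i in 1:2) {
    env_range <- range(envelopes[[i]]$mass) - .proton_mass
    if (env_range[1] < mz_range[1] || env_range[2] > mz_range[2])
      stop("mz_range must contain the '", targets[[i]]$name,
           "' isotope envelope (", round(env_range[1], 2), "-",
           round(env_range[2], 2), ")")
  }
  structure(list(regions = regions, mz_range = mz_range, mz_bin = mz_bin,
                 peak_sigma = peak_sigma, baseline = baseline,
                 gain_sdlog = gain_sdlog, noise_sd = noise_sd,
                 animal_cv = animal_cv, n_animals = as.integer(n_animals),
                 sections_per_animal = as.integer(sections_per_animal),
                 hemispheres = hemispheres,
                 drop_roi_rate = drop_roi_rate, seed = as.integer(seed),
                 targets = targets, envelopes = envelopes),
            class = "sim_config")
}

.sim_axis <- function(config) {
  seq(config$mz_range[1], config$mz_range[2], by = config$mz_bin)
}

# abundances (A18, A20) giving an expected highest-peak AUC ratio of
# `ratio`, correcting for the species' monoisotopic envelope fractions
.species_abundances <- function(config, region, ratio_multiplier = 1) {
  r <- config$regions[[region]]
  if (is.null(r)) stop("region '", region, "' not declared in config")
  ratio <- r$ratio * ratio_multiplier
  f1 <- config$envelopes[[1]]$abundance[1]
  f2 <- config$envelopes[[2]]$abundance[1]
  rho <- ratio * f2 / f1
  c(r$total * rho / (1 + rho), r$total / (1 + rho))
}

# noiseless species signal on the axis: sum over species and isotope peaks
# of abundance-weighted Gaussians centered at the [M-H]- peak masses
.signal_vector <- function(config, abundances, axis = .sim_axis(config)) {
  signal <- numeric(length(axis))
  for (i in seq_along(config$envelopes)) {
    env <- config$envelopes[[i]]
    for (j in seq_along(env$mass)) {
      ctr <- env$mass[j] - .proton_mass
      win <- which(axis >= ctr - 8 * config$peak_sigma &
                   axis <= ctr + 8 * config$peak_sigma)
      if (!length(win)) next
      signal[win] <- signal[win] + abundances[i] * env$abundance[j] *
        stats::dnorm(axis[win], ctr, config$peak_sigma)
    }
  }
  signal
}

.baseline_vector <- function(config, axis = .sim_axis(config)) {
  b <- config$baseline
  b$constant + b$slope * (axis - config$mz_range[1]) +
    b$bump_amplitude * exp(-((axis - b$bump_center)^2) / (2 * b$bump_sd^2))
}

#' Simulate one pixel's mass spectrum
#'
#' intensity(m/z) = gain x species signal + baseline + noise, clipped at 0,
#' where gain is a lognormal per-pixel draw and noise is additive Gaussian.
#' Consumes the current RNG state; seed beforehand for reproducibility.
#'
#' @param config A [sim_config()].
#' @param region Declared region label.
#' @param ratio_multiplier Per-animal multiplier on the region's true ratio.
#' @return A [mass_spectrum()].
#' @export
simulate_pixel_spectrum <- function(config, region, ratio_multiplier = 1) {
  axis <- .sim_axis(config)
  ab <- .species_abundances(config, region, ratio_multiplier)
  gain <- if (config$gain_sdlog > 0) stats::rlnorm(1, 0, config$gain_sdlog)
          else 1
  intensity <- gain * .signal_vector(config, ab, axis) +
    .baseline_vector(config, axis)
  if (config$noise_sd > 0)
    intensity <- intensity + stats::rnorm(length(axis), 0, config$noise_sd)
  mass_spectrum(axis, pmax(intensity, 0))
}

# one animal-section dataset over the mirrored tissue grid; labels is the
# per-pixel region vector, multipliers the animal's per-region ratio factors
.simulate_dataset <- function(config, coords, labels, multipliers,
                              pixel_pitch, dataset_id) {
  axis <- .sim_axis(config)
  n_px <- nrow(coords)
  ints <- matrix(.baseline_vector(config, axis), n_px, length(axis),
                 byrow = TRUE)
  gains <- if (config$gain_sdlog > 0)
    stats::rlnorm(n_px, 0, config$gain_sdlog) else rep(1, n_px)
  for (rg in unique(labels)) {
    idx <- which(labels == rg)
    sig <- .signal_vector(config, .species_abundances(config, rg,
                                                      multipliers[[rg]]),
                          axis)
    nz <- which(sig > 0)
    if (length(nz))
      ints[idx, nz] <- ints[idx, nz] + outer(gains[idx], sig[nz])
  }
  if (config$noise_sd > 0)
    ints <- ints + matrix(stats::rnorm(n_px * length(axis), 0,
                                       config$noise_sd),
                          n_px, length(axis))
  ints[ints < 0] <- 0
  ims_dataset(coords, axis, ints, pixel_pitch = pixel_pitch,
              metadata = list(id = dataset_id, gains = gains))
}

#' Simulate a complete imaging study
#'
#' One dataset per animal-section over the left/right-mirrored phantom, one
#' ROI per region, hemisphere and section, and a ground-truth record
#' sufficient to recompute the expectation of every pipeline output. All
#' randomness derives from `config$seed` (per-animal ratio multipliers and
#' ROI drops from the master stream; a deterministic child seed per
#' animal-section dataset), so a fixed seed reproduces the study exactly.
#'
#' @param config A [sim_config()].
#' @param phantom A [region_map()] for one hemisphere; every declared config
#'   region that appears in the phantom is simulated.
#' @return List with `datasets` (named list of [ims_dataset()]), `rois`
#'   (list of [ims_roi()]), `truth` (ground-truth list) and the inputs.
#' @export
simulate_study <- function(config, phantom) {
  stopifnot(inherits(config, "sim_config"), inherits(phantom, "region_map"))
  missing_rg <- setdiff(phantom$regions, names(config$regions))
  if (length(missing_rg))
    stop("phantom regions not declared in config: ",
         paste(missing_rg, collapse = ", "))

  grid_l <- phantom$grid
  use_right <- "right" %in% config$hemispheres
  grid <- if (use_right) cbind(grid_l, grid_l[, rev(seq_len(ncol(grid_l))),
                                              drop = FALSE])
          else grid_l
  hemi_of_col <- c(rep("left", ncol(grid_l)),
                   if (use_right) rep("right", ncol(grid_l)))
  on_tissue <- which(!is.na(grid))  # column-major
  px_row <- (on_tissue - 1L) %% nrow(grid)
  px_col <- (on_tissue - 1L) %/% nrow(grid)
  coords <- data.frame(x = px_col, y = px_row)
  labels <- grid[on_tissue]
  hemis <- hemi_of_col[px_col + 1L]

  set.seed(config$seed)
  sdlog <- sqrt(log(1 + config$animal_cv^2))
  mult <- matrix(if (config$animal_cv > 0)
      stats::rlnorm(config$n_animals * length(phantom$regions),
                    -sdlog^2 / 2, sdlog)
    else 1,
    nrow = config$n_animals, ncol = length(phantom$regions),
    dimnames = list(NULL, phantom$regions))
  n_ds <- config$n_animals * config$sections_per_animal
  child_seeds <- sample.int(.Machine$integer.max, n_ds)
  n_roi_slots <- n_ds * length(config$hemispheres) * length(phantom$regions)
  drop_u <- stats::runif(n_roi_slots)

  datasets <- list(); rois <- list(); slot <- 0L; k <- 0L
  for (a in seq_len(config$n_animals)) {
    animal_id <- sprintf("A%02d", a)
    for (s in seq_len(config$sections_per_animal)) {
      k <- k + 1L
      section_id <- sprintf("S%d", s)
      dataset_id <- paste(animal_id, section_id, sep = "_")
      set.seed(child_seeds[k])
      datasets[[dataset_id]] <- .simulate_dataset(
        config, coords, labels, as.list(mult[a, ]), phantom$pixel_pitch,
        dataset_id)
      for (h in config$hemispheres) {
        for (rg in phantom$regions) {
          slot <- slot + 1L
          if (drop_u[slot] < config$drop_roi_rate) next
          px <- which(labels == rg & hemis == h)
          rois[[length(rois) + 1L]] <- ims_roi(
            px, region = rg, hemisphere = h, section_id = section_id,
            animal_id = animal_id, dataset_id = dataset_id)
        }
      }
    }
  }

  truth <- list(
    seed = config$seed,
    regions = lapply(config$regions, function(r)
      list(true_ratio = r$ratio, total = r$total)),
    animal_ratio_multipliers = as.data.frame(mult),
    animal_cv = config$animal_cv,
    gain_sdlog = config$gain_sdlog, noise_sd = config$noise_sd,
    n_animals = config$n_animals,
    sections_per_animal = config$sections_per_animal,
    hemispheres = config$hemispheres)

  list(datasets = datasets, rois = rois, truth = truth,
       config = config, phantom = phantom)
}
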