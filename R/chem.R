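# Molecular-formula arithmetic, monoisotopic [M-H]- m/z prediction and
# isotope-envelope computation for GM1 ganglioside species.

# Static isotope table (IUPAC 2021 atomic masses / representative natural
# abundances). Columns: nucleon offset from the lightest isotope, exact mass
# (Da), natural abundance. Extensible: add rows for further elements.
.isotope_table <- list(
  H  = data.frame(delta = c(0L, 1L),
                  mass = c(1.00782503224, 2.01410177812),
                  abundance = c(0.999885, 0.000115)),
  C  = data.frame(delta = c(0L, 1L),
                  mass = c(12.0, 13.00335483521),
                  abundance = c(0.9893, 0.0107)),
  N  = data.frame(delta = c(0L, 1L),
                  mass = c(14.00307400446, 15.00010889894),
                  abundance = c(0.99636, 0.00364)),
  O  = data.frame(delta = c(0L, 1L, 2L),
                  mass = c(15.99491461960, 16.99913175664, 17.99915961284),
                  abundance = c(0.99757, 0.00038, 0.00205)),
  P  = data.frame(delta = 0L, mass = 30.97376199857, abundance = 1.0),
  S  = data.frame(delta = c(0L, 1L, 2L, 4L),
                  mass = c(31.97207117443, 32.97145890985, 33.96786701200,
                           35.96708070000),
                  abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Na = data.frame(delta = 0L, mass = 22.98976928199, abundance = 1.0),
  K  = data.frame(delta = c(0L, 1L, 2L),
                  mass = c(38.96370648482, 39.96399817000, 40.96182525796),
                  abundance = c(0.932581, 0.000117, 0.067302))
)

# Mass of the proton; [M-H]- m/z = neutral monoisotopic mass - proton mass
# (electron mass deliberately ignored: the ~0.0005 Da error is far below the
# 2-decimal reporting precision of the targeted species).
.proton_mass <- 1.007276466621

#' Parse a molecular formula in Hill notation
#'
#' @param formula A character scalar such as `"C73H131N3O31"`, or an already
#'   parsed named integer vector (returned unchanged after validation).
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("H2O")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    counts <- formula
    if (is.null(names(counts)) || any(!nzchar(names(counts))))
      stop("numeric formula must be a named vector of element counts")
  } else {
    if (!is.character(formula) || length(formula) != 1L || !nzchar(formula))
      stop("formula must be a single non-empty string")
    tokens <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
    parts <- regmatches(formula, list(tokens))[[1]]
    if (sum(nchar(parts)) != nchar(formula))
      stop("malformed formula string: ", formula)
    els <- sub("[0-9]+$", "", parts)
    ns <- as.integer(ifelse(grepl("[0-9]+$", parts),
                            sub("^[A-Za-z]+", "", parts), "1"))
    counts <- tapply(ns, els, sum)
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  unknown <- setdiff(names(counts), names(.isotope_table))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  if (any(counts < 1) || any(counts != round(counts)))
    stop("element counts must be positive integers")
  storage.mode(counts) <- "integer"
  counts
}

#' Neutral monoisotopic mass of a molecular formula
#'
#' Sums the lightest-isotope atomic masses of all atoms.
#'
#' @inheritParams parse_formula
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(vapply(names(counts), function(el) {
    .isotope_table[[el]]$mass[1]
  }, numeric(1)) * counts)
}

#' Predicted m/z of an ion
#'
#' For the deprotonated ion `[M-H]-` (the only adduct required for negative
#' ion mode ganglioside imaging) the m/z is the neutral monoisotopic mass
#' minus one proton mass; the electron mass is ignored.
#'
#' @inheritParams parse_formula
#' @param adduct Ion type; only `"[M-H]-"` is supported.
#' @return m/z in Da.
#' @examples
#' monoisotopic_mz("C73H131N3O31")  # GM1 d18:1 (stearoyl), ~1544.87
#' @export
monoisotopic_mz <- function(formula, adduct = "[M-H]-") {
  counts <- parse_formula(formula)
  adduct <- match.arg(adduct, "[M-H]-")
  if (!("H" %in% names(counts)))
    stop("[M-H]- requires at least one hydrogen in the formula")
  monoisotopic_mass(counts) - .proton_mass
}

#' Aggregated isotope envelope of a molecular formula
#'
#' Computes the nucleon-number-aggregated (unit-mass) isotope distribution by
#' per-element multinomial convolution: fine structure within a nucleon
#' number is collapsed to its abundance-weighted mean mass, which is the
#' resolution regime of reflectron TOF data at m/z > 1000.
#'
#' @inheritParams parse_formula
#' @param max_peaks Number of envelope peaks to keep (>= 1).
#' @param normalize `"sum"` for sum-to-one abundances, `"base"` for
#'   base-peak-to-one.
#' @return Object of class `isotope_envelope`: list with `mass` (Da,
#'   strictly increasing), `abundance`, and `normalize`.
#' @export
isotope_envelope <- function(formula, max_peaks = 6L,
                             normalize = c("sum", "base")) {
  counts <- parse_formula(formula)
  normalize <- match.arg(normalize)
  if (max_peaks < 1L) stop("max_peaks must be >= 1")
  width <- as.integer(max_peaks + 4L)  # headroom before truncation

  # distribution over nucleon offset k: prob[k+1] and massnum[k+1] =
  # sum over isotopologues at offset k of (prob * total mass)
  conv <- function(a, b) {
    n <- min(width, length(a$prob) + length(b$prob) - 1L)
    prob <- numeric(n); massnum <- numeric(n)
    for (i in seq_along(a$prob)) {
      jmax <- min(length(b$prob), n - i + 1L)
      if (jmax < 1L) next
      j <- seq_len(jmax)
      prob[i + j - 1L] <- prob[i + j - 1L] + a$prob[i] * b$prob[j]
      massnum[i + j - 1L] <- massnum[i + j - 1L] +
        a$prob[i] * b$massnum[j] + a$massnum[i] * b$prob[j]
    }
    list(prob = prob, massnum = massnum)
  }

  dist <- list(prob = 1, massnum = 0)
  for (el in names(counts)) {
    iso <- .isotope_table[[el]]
    atom <- list(prob = numeric(max(iso$delta) + 1L),
                 massnum = numeric(max(iso$delta) + 1L))
    atom$prob[iso$delta + 1L] <- iso$abundance
    atom$massnum[iso$delta + 1L] <- iso$abundance * iso$mass
    # n-fold self-convolution by binary exponentiation
    n <- counts[[el]]
    acc <- NULL
    base <- atom
    while (n > 0L) {
      if (n %% 2L == 1L) acc <- if (is.null(acc)) base else conv(acc, base)
      n <- n %/% 2L
      if (n > 0L) base <- conv(base, base)
    }
    dist <- conv(dist, acc)
  }

  keep <- which(dist$prob > 0)
  keep <- keep[seq_len(min(length(keep), max_peaks))]
  mass <- dist$massnum[keep] / dist$prob[keep]
  ab <- dist$prob[keep]
  ab <- switch(normalize, sum = ab / sum(ab), base = ab / max(ab))
  structure(list(mass = mass, abundance = ab, normalize = normalize),
            class = "isotope_envelope")
}

#' @export
print.isotope_envelope <- function(x, ...) {
  cat("Isotope envelope (", x$normalize, "-normalized):\n", sep = "")
  print(data.frame(mass = x$mass, abundance = x$abundance))
  invisible(x)
}

#' Define a targeted species
#'
#' A `species_target` couples a name and molecular formula with the predicted
#' `[M-H]-` m/z and the m/z windows used to search for and integrate its
#' highest (monoisotopic) peak.
#'
#' @param name Species label, e.g. `"GM1d18:1"`.
#' @param formula Molecular formula (Hill notation string or named vector).
#' @param adduct Ion type; only `"[M-H]-"`.
#' @param predicted_mz Optional override of the computed m/z (Da).
#' @param search_halfwidth Half-width (Da) of the apex search window around
#'   `predicted_mz`; the default 0.5 Da is half an isotope spacing, so the
#'   monoisotopic peak is always the one selected.
#' @param integration_halfwidth Half-width (Da) of the AUC integration window
#'   around the apex; the default 0.4 Da stays within one isotope spacing so
#'   only the highest peak is integrated.
#' @return Object of class `species_target`.
#' @export
species_target <- function(name, formula, adduct = "[M-H]-",
                           predicted_mz = NULL,
                           search_halfwidth = 0.5,
                           integration_halfwidth = 0.4) {
  counts <- parse_formula(formula)
  if (is.null(predicted_mz)) predicted_mz <- monoisotopic_mz(counts, adduct)
  stopifnot(predicted_mz > 0, search_halfwidth > 0, integration_halfwidth > 0)
  structure(list(name = name, formula = counts, adduct = adduct,
                 predicted_mz = predicted_mz,
                 search_halfwidth = search_halfwidth,
                 integration_halfwidth = integration_halfwidth),
            class = "species_target")
}

#' Default GM1 species targets
#'
#' The two GM1 species targeted by the pipeline, assuming a stearoyl (18:0)
#' fatty acid on both ceramides: GM1 d18:1 (C73H131N3O31, `[M-H]-` at
#' ~1544.87) and GM1 d20:1 (C75H135N3O31, ~1572.90). The formulas are the
#' standard compositions consistent with these targeted m/z values; the 18:0
#' acyl assumption is a documented convention, not a measurement.
#'
#' @param ... Passed to [species_target()] (e.g. window half-widths).
#' @return Named list of two `species_target` objects, `d18` and `d20`.
#' @export
gm1_species_targets <- function(...) {
  list(d18 = species_target("GM1d18:1", "C73H131N3O31", ...),
       d20 = species_target("GM1d20:1", "C75H135N3O31", ...))
}
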