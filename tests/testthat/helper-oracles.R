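# Independent oracles and small fixture builders used across the suite.

# Exhaustive isotopologue enumeration: every atom is assigned one isotope,
# probabilities multiply, nucleon offsets add. Feasible for <= 10 atoms.
brute_force_envelope <- function(formula, max_peaks = 6L) {
  counts <- parse_formula(formula)
  iso <- gm1ims:::.isotope_table
  atoms <- rep(names(counts), counts)
  stopifnot(length(atoms) <= 10L)
  choices <- expand.grid(lapply(atoms, function(el)
    seq_len(nrow(iso[[el]]))), KEEP.OUT.ATTRS = FALSE)
  prob <- rep(1, nrow(choices)); mass <- numeric(nrow(choices))
  delta <- integer(nrow(choices))
  for (j in seq_along(atoms)) {
    tab <- iso[[atoms[j]]]
    k <- choices[[j]]
    prob <- prob * tab$abundance[k]
    mass <- mass + tab$mass[k]
    delta <- delta + tab$delta[k]
  }
  agg_p <- tapply(prob, delta, sum)
  agg_m <- tapply(prob * mass, delta, sum) / agg_p
  ord <- order(as.integer(names(agg_p)))
  keep <- ord[seq_len(min(length(ord), max_peaks))]
  list(mass = as.numeric(agg_m[keep]),
       abundance = as.numeric(agg_p[keep]) / sum(agg_p[keep]))
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
mw_enumeration_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); N <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(N, n1), 2, u_of)
  mu <- n1 * (N - n1) / 2
  mean(abs(all_u - mu) >= abs(obs - mu))
}

# Spectrum of Gaussian peaks on an arbitrary baseline.
gaussian_spectrum <- function(mz, centers, amplitudes, sigma = 0.15,
                              baseline = 0) {
  y <- rep_len(baseline, length(mz))
  for (i in seq_along(centers))
    y <- y + amplitudes[i] * stats::dnorm(mz, centers[i], sigma)
  mass_spectrum(mz, pmax(y, 0))
}

# Small fast study: defaults sized for unit tests, not for recovery power.
tiny_config <- function(regions, n_animals = 2L, seed = 1L, ...) {
  sim_config(regions = regions, mz_range = c(1500, 1620),
             n_animals = n_animals, seed = seed, ...)
}
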