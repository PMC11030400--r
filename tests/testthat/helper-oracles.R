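# Independent oracles, deliberately implemented differently from the package.

# Exhaustive isotopologue enumeration: for each element, enumerate every
# heavy-isotope count vector, weight by the multinomial probability, and
# accumulate by nucleon shift; combine elements by full convolution.
enum_envelope <- function(counts, n_peaks = 3) {
  ab <- list(C = c(0.9893, 0.0107),
             H = c(0.999885, 0.000115),
             N = c(0.99636, 0.00364),
             O = c(0.99757, 0.00038, 0.00205),
             S = c(0.9499, 0.0075, 0.0425, 0, 0.0001))
  dist <- c(1)
  for (el in names(ab)) {
    n <- counts[[el]]
    if (is.na(n) || n == 0) next
    p <- ab[[el]]
    k <- length(p)
    combos <- expand.grid(rep(list(0:n), k - 1))
    el_dist <- numeric(0)
    for (i in seq_len(nrow(combos))) {
      heavy <- as.integer(combos[i, ])
      if (sum(heavy) > n) next
      cnt <- c(n - sum(heavy), heavy)
      prob <- suppressWarnings(dmultinom(cnt, prob = p))
      shift <- sum(heavy * seq_len(k - 1))
      if (shift + 1 > length(el_dist))
        el_dist <- c(el_dist, numeric(shift + 1 - length(el_dist)))
      el_dist[shift + 1] <- el_dist[shift + 1] + prob
    }
    new <- numeric(length(dist) + length(el_dist) - 1)
    for (i in seq_along(dist)) for (j in seq_along(el_dist))
      new[i + j - 1] <- new[i + j - 1] + dist[i] * el_dist[j]
    dist <- new
  }
  d <- dist[seq_len(min(n_peaks, length(dist)))]
  if (length(d) < n_peaks) d <- c(d, numeric(n_peaks - length(d)))
  d / sum(d)
}

# Monoisotopic residue masses (independent of the package's element tables).
RESIDUE_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

peptide_mono_mass_oracle <- function(sequence) {
  sum(RESIDUE_MONO_MASS[strsplit(sequence, "")[[1]]]) + 18.01056
}

random_small_composition <- function() {
  # compositions no larger than C10H20N2O5S
  counts <- c(C = sample(0:10, 1), H = sample(0:20, 1), N = sample(0:2, 1),
              O = sample(0:5, 1), S = sample(0:1, 1))
  if (sum(counts) == 0) counts["C"] <- 1
  counts
}

# package-independent composition object for isotope_distribution()
as_composition <- function(counts) {
  structure(list(counts = counts, labeled = c(C = 0L, N = 0L)),
            class = "elemental_composition")
}
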