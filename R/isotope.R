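## isotope: elemental compositions, theoretical isotope envelopes, and the
## isotope dot product (idotp) used to detect loss of the M+1/M+2 13C peaks.

## Natural isotope abundances, indexed by nucleon offset from the lightest
## isotope (0, +1, +2, ...). Values follow the IUPAC 2013 representative
## abundances; they are frozen here so envelopes are reproducible without an
## external element database.
ISOTOPE_ABUNDANCE <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

## Monoisotopic element masses (Da).
ELEMENT_MONO_MASS <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
                       O = 15.9949146196, S = 31.97207100)
PROTON_MASS <- 1.007276467

## Elemental composition of each amino-acid residue (peptide-bond form,
## i.e. the free amino acid minus one water).
RESIDUE_COMPOSITIONS <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1, S = 0),
  A = c(C = 3,  H = 5,  N = 1, O = 1, S = 0),
  S = c(C = 3,  H = 5,  N = 1, O = 2, S = 0),
  P = c(C = 5,  H = 7,  N = 1, O = 1, S = 0),
  V = c(C = 5,  H = 9,  N = 1, O = 1, S = 0),
  T = c(C = 4,  H = 7,  N = 1, O = 2, S = 0),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4,  H = 6,  N = 2, O = 2, S = 0),
  D = c(C = 4,  H = 5,  N = 1, O = 3, S = 0),
  Q = c(C = 5,  H = 8,  N = 2, O = 2, S = 0),
  K = c(C = 6,  H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5,  H = 7,  N = 1, O = 3, S = 0),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1, S = 0),
  F = c(C = 9,  H = 9,  N = 1, O = 1, S = 0),
  R = c(C = 6,  H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9,  H = 9,  N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

new_composition <- function(counts, labeled = c(C = 0L, N = 0L)) {
  structure(list(counts = counts, labeled = labeled),
            class = "elemental_composition")
}

#' Elemental composition of a peptide
#'
#' Sums per-residue compositions and one water. Carbamidomethylation adds
#' C2H3NO per cysteine. The stable-isotope label used by common synthetic
#' retention-time peptide mixtures (13C6,15N2 on C-terminal K; 13C6,15N4 on
#' C-terminal R) is tracked as a count of atoms pinned to their heavy
#' isotope; those atoms are excluded from the natural-abundance pools when an
#' envelope is computed, since a fully labeled atom contributes a constant
#' mass shift but no envelope spread.
#'
#' @param sequence Peptide as an uppercase string of 1-letter residue codes.
#' @param fixed_mods Character vector of fixed modifications; only
#'   `"CARBAMIDOMETHYL_C"` is recognised.
#' @param heavy_label `"NONE"` or `"LABEL_13C6_15N2_K_and_13C6_15N4_R"`.
#' @return An `elemental_composition`: element counts (C, H, N, O, S) plus a
#'   `labeled` annotation with the number of 13C and 15N atoms.
#' @examples
#' peptide_composition("GG")          # C4 H8 N2 O3
#' monoisotopic_mass(peptide_composition("LVNELTEFAK"))
#' @export
peptide_composition <- function(sequence,
                                fixed_mods = character(),
                                heavy_label = c("NONE", "LABEL_13C6_15N2_K_and_13C6_15N4_R")) {
  heavy_label <- match.arg(heavy_label)
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0)
    qcs_argument_error("sequence must be a single non-empty string")
  residues <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(residues, names(RESIDUE_COMPOSITIONS))
  if (length(unknown) > 0)
    qcs_validation_error(paste0("unknown residue character(s): ",
                                paste(unique(unknown), collapse = ", ")))
  counts <- c(C = 0, H = 2, N = 0, O = 1, S = 0)  # start from one water
  for (r in residues) counts <- counts + RESIDUE_COMPOSITIONS[[r]]
  if ("CARBAMIDOMETHYL_C" %in% fixed_mods) {
    ncys <- sum(residues == "C")
    counts <- counts + ncys * c(C = 2, H = 3, N = 1, O = 1, S = 0)
  }
  labeled <- c(C = 0L, N = 0L)
  if (heavy_label == "LABEL_13C6_15N2_K_and_13C6_15N4_R") {
    last <- residues[length(residues)]
    if (last == "K") labeled <- c(C = 6L, N = 2L)
    else if (last == "R") labeled <- c(C = 6L, N = 4L)
    else warn("heavy label requested but peptide does not end in K or R; no atoms labeled")
  }
  new_composition(counts, labeled)
}

#' Monoisotopic mass of a composition
#'
#' @param comp An `elemental_composition`.
#' @param charge If `> 0`, returns the m/z of the `[M + charge*H]^charge+`
#'   ion; `0` (default) returns the neutral monoisotopic mass. Heavy-labeled
#'   atoms contribute their 13C/15N masses.
#' @return Mass in Da (or m/z).
#' @export
monoisotopic_mass <- function(comp, charge = 0) {
  m <- sum(comp$counts * ELEMENT_MONO_MASS[names(comp$counts)])
  ## +1 neutron-ish shift per labeled atom: 13C - 12C and 15N - 14N
  m <- m + comp$labeled[["C"]] * (13.00335483507 - 12) +
    comp$labeled[["N"]] * (15.0001088989 - 14.0030740048)
  if (charge > 0) m <- (m + charge * PROTON_MASS) / charge
  unname(m)
}

## Truncated convolution of two nucleon-offset probability vectors.
convolve_trunc <- function(a, b, n) {
  out <- numeric(n)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    jmax <- min(length(b), n - i + 1)
    if (jmax < 1) break
    idx <- i + seq_len(jmax) - 1L
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

## dist^m under truncated convolution, by binary exponentiation.
convolve_power <- function(dist, m, n) {
  result <- c(1, numeric(n - 1))
  base <- c(dist, numeric(max(0, n - length(dist))))[seq_len(max(n, length(dist)))]
  base <- base[seq_len(n)] / 1  # keep first n offsets; tail mass is truncated
  while (m > 0) {
    if (m %% 2 == 1) result <- convolve_trunc(result, base, n)
    base <- convolve_trunc(base, base, n)
    m <- m %/% 2
  }
  result
}

#' Theoretical aggregated isotope envelope
#'
#' Computes the nucleon-number (M0, M+1, M+2, ...) envelope of a composition
#' by iterated elementwise convolution of the per-element isotope
#' distributions, truncates it to `n_peaks`, and renormalizes to sum to 1.
#' Atoms pinned to a heavy isotope by a label are excluded from convolution
#' (they shift every peak equally and do not change the envelope shape).
#'
#' @param comp An `elemental_composition`.
#' @param n_peaks Number of peaks to keep (default 3: M0, M+1, M+2).
#' @return An `isotope_envelope`: numeric vector of length `n_peaks` summing
#'   to 1, with attributes `coverage` (probability mass captured before
#'   renormalization) and `renormalized`.
#' @export
isotope_distribution <- function(comp, n_peaks = 3L) {
  if (!is.numeric(n_peaks) || n_peaks < 1)
    qcs_argument_error("n_peaks must be an integer >= 1")
  n_peaks <- as.integer(n_peaks)
  counts <- comp$counts
  counts["C"] <- counts["C"] - comp$labeled[["C"]]
  counts["N"] <- counts["N"] - comp$labeled[["N"]]
  if (any(counts < 0))
    qcs_validation_error("labeled atom count exceeds element count")
  env <- c(1, numeric(n_peaks - 1))
  for (el in names(ISOTOPE_ABUNDANCE)) {
    m <- counts[[el]]
    if (is.na(m) || m == 0) next
    env <- convolve_trunc(env, convolve_power(ISOTOPE_ABUNDANCE[[el]], m, n_peaks), n_peaks)
  }
  coverage <- sum(env)
  structure(env / coverage, coverage = coverage,
            renormalized = coverage < 1,
            class = "isotope_envelope")
}

#' Isotope dot product
#'
#' Normalized dot product (cosine similarity) between an expected isotope
#' envelope and observed isotope-peak abundances. Equals 1 iff the vectors
#' are proportional, is invariant to positive rescaling of either argument,
#' and decreases monotonically as the heavy peaks are attenuated while M0 is
#' held fixed. An optional square-root transform of both vectors is offered
#' because some integration software weights peaks that way; the default is
#' the plain cosine on untransformed abundances.
#'
#' @param expected Numeric vector (e.g. an `isotope_envelope`).
#' @param observed Numeric vector of the same length, non-negative, not all
#'   zero.
#' @param transform `"none"` (default) or `"sqrt"`.
#' @return A number in `[0, 1]`.
#' @export
idotp <- function(expected, observed, transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  e <- as.numeric(expected); o <- as.numeric(observed)
  if (length(e) != length(o) || length(e) < 2)
    qcs_argument_error("expected and observed must have equal length >= 2")
  if (any(is.na(e)) || any(is.na(o)))
    qcs_argument_error("idotp inputs must be finite")
  if (any(e < 0) || any(o < 0))
    qcs_argument_error("idotp inputs must be non-negative")
  if (all(o == 0))
    stop_qcs("observed isotope areas are all zero; idotp is undefined",
             "qcs_undefined_score_error")
  if (all(e == 0))
    stop_qcs("expected envelope is all zero; idotp is undefined",
             "qcs_undefined_score_error")
  if (transform == "sqrt") { e <- sqrt(e); o <- sqrt(o) }
  min(1, sum(e * o) / sqrt(sum(e^2) * sum(o^2)))
}
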