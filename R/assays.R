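# qPCR and molecular-beacon arithmetic
#
# Pfaffl efficiency-corrected relative expression, amplification-efficiency
# estimation from the window-of-linearity of log fluorescence, and a
# two-state nearest-neighbor melting temperature for beacon hairpins.

#' Pfaffl relative expression ratio
#'
#' `eff_tar^dct_tar / eff_ref^dct_ref`, with delta-ct in the (control -
#' test) convention for both genes.
#'
#' @param eff_tar,eff_ref amplification efficiencies in fold per cycle
#'   (1 < eff <= 2 for real assays; any positive value is accepted).
#' @param dct_tar,dct_ref delta-ct (control - test) in cycles.
#' @return dimensionless expression ratio.
#' @export
pfaffl_ratio <- function(eff_tar, dct_tar, eff_ref, dct_ref) {
  if (eff_tar <= 0 || eff_ref <= 0) stop("efficiencies must be positive")
  eff_tar^dct_tar / eff_ref^dct_ref
}

#' Amplification efficiency from a fluorescence curve
#'
#' Fits log10(fluorescence) against cycle over every contiguous window of
#' `window` cycles with positive fluorescence, keeps the window with the
#' best coefficient of determination among those with positive slope
#' (earliest window on ties), and returns `10^slope` as fold per cycle.
#' Baseline and plateau cycles lose by linearity.
#'
#' @param cycles integer cycle numbers.
#' @param fluorescence non-negative readings, parallel to `cycles`.
#' @param window points per regression window (default 5).
#' @return list with `efficiency`, `window` (cycle range used) and
#'   `r_squared`.
#' @export
amplification_efficiency <- function(cycles, fluorescence, window = 5) {
  if (length(cycles) != length(fluorescence)) {
    stop("cycles and fluorescence must be parallel")
  }
  if (length(cycles) < max(6, window)) stop("need at least 6 curve points")
  best <- NULL
  for (s in seq_len(length(cycles) - window + 1)) {
    idx <- s:(s + window - 1)
    f <- fluorescence[idx]
    if (any(f <= 0)) next
    x <- cycles[idx]
    y <- log10(f)
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- unname(fit$coefficients[2])
    if (!is.finite(slope) || slope <= 1e-6) next
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot < 1e-12) next  # flat window (baseline/plateau), not exponential
    r2 <- 1 - ss_res / ss_tot
    if (is.null(best) || r2 > best$r_squared + 1e-12) {
      best <- list(efficiency = 10^slope, window = range(x), r_squared = r2)
    }
  }
  if (is.null(best)) {
    stop("no window with a positive log-linear slope; curve has no ",
         "exponential segment")
  }
  best
}

# Unified nearest-neighbor parameters for DNA duplex stacks at 1 M NaCl
# (dH kcal/mol, dS cal/mol/K), keyed by the 5'->3' top-strand dinucleotide.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
NN_EQUIV <- c(TT = "AA", TG = "CA", AC = "GT", AG = "CT", TC = "GA",
              CC = "GG")

revcomp_dna <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

nn_lookup <- function(dinuc, table) {
  key <- ifelse(dinuc %in% names(table), dinuc, NN_EQUIV[dinuc])
  unname(table[key])
}

# hairpin loop free-energy penalty at 37 C (kcal/mol), Jacobson-Stockmayer
# extrapolated beyond 9 nt; treated as purely entropic
hairpin_loop_dg37 <- function(loop_len) {
  base <- c(`3` = 3.5, `4` = 3.5, `5` = 3.3, `6` = 4.0, `7` = 4.2,
            `8` = 4.3, `9` = 4.4)
  if (loop_len <= 9) return(unname(base[as.character(loop_len)]))
  unname(base["9"]) + 1.75 * 0.0019872 * 310.15 * log(loop_len / 9)
}

#' Stem-loop (hairpin) melting temperature
#'
#' Detects the longest self-complementary stem formed by the 5' and 3'
#' termini, sums unified nearest-neighbor enthalpies/entropies over the stem
#' stacks (with terminal-AT penalties), adds a hairpin-loop entropic penalty
#' and an entropic salt correction, and returns the two-state unimolecular
#' melting temperature `Tm = dH/dS - 273.15`.
#'
#' @param sequence 5'->3' DNA string (A/C/G/T).
#' @param stem_length stem length in bp; detected from the termini when
#'   `NULL`, validated against the sequence when given.
#' @param na_molar monovalent salt (mol/L); parameters are referenced to
#'   1 M, lower salt lowers Tm.
#' @return list with `tm_celsius`, `stem_length`, `loop_length`, `dh`
#'   (kcal/mol) and `ds` (cal/mol/K).
#' @export
hairpin_tm <- function(sequence, stem_length = NULL, na_molar = 1.0) {
  s <- toupper(gsub("[^ACGT]", "", toupper(sequence)))
  if (nchar(s) != nchar(gsub("\\s", "", sequence))) {
    stop("sequence must be A/C/G/T only")
  }
  n <- nchar(s)
  max_stem <- (n - 3) %/% 2
  detect <- function(L) {
    substr(s, 1, L) == revcomp_dna(substr(s, n - L + 1, n))
  }
  if (is.null(stem_length)) {
    stem_length <- 0
    for (L in seq_len(max_stem)) if (detect(L)) stem_length <- L
    if (stem_length == 0) stop("termini are not self-complementary")
  } else if (stem_length < 1 || stem_length > max_stem || !detect(stem_length)) {
    stop("termini do not form a ", stem_length, "-bp stem")
  }
  loop_len <- n - 2 * stem_length
  if (loop_len < 3) stop("loop must be >= 3 nt")
  stem <- substr(s, 1, stem_length)
  letters <- strsplit(stem, "")[[1]]
  dh <- 0; ds <- 0
  if (stem_length >= 2) {
    dinucs <- paste0(letters[-stem_length], letters[-1])
    dh <- sum(nn_lookup(dinucs, NN_DH))
    ds <- sum(nn_lookup(dinucs, NN_DS))
  }
  # terminal AT penalty on the outer closing pair
  if (letters[1] %in% c("A", "T")) { dh <- dh + 2.3; ds <- ds + 4.1 }
  # loop penalty, entropic
  ds <- ds - hairpin_loop_dg37(loop_len) * 1000 / 310.15
  # entropic salt correction over stem phosphates
  if (na_molar <= 0) stop("na_molar must be positive")
  ds <- ds + 0.368 * (stem_length - 1) * log(na_molar)
  if (ds >= 0) stop("non-negative total entropy; no two-state transition")
  tm_k <- dh * 1000 / ds
  list(tm_celsius = tm_k - 273.15, stem_length = stem_length,
       loop_length = loop_len, dh = dh, ds = ds)
}
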