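# Intrinsic disorder from Boltzmann-inverted pairwise potentials
#
# The scorer follows the energy-estimation idea behind pairwise
# disorder predictors: a dimensionless interaction energy
# E_ij = -ln(rho_ij / rho*_ij) is extracted from observed vs reference
# amino-acid pairing frequencies (Boltzmann inversion), a per-residue
# energy is the composition-weighted window average of E, and a monotone
# increasing logistic maps energy to a disorder score in [0, 1] (favourable,
# low energy -> low disorder). Published per-protein score curves depend on
# the original predictor's fitted parameter set; this module is validated on
# ordering properties and also accepts externally computed scores (TSV) so
# printed domain averages can be used verbatim downstream.

# Synthetic calibration pair: an ordered-like hydrophobic-core sequence and
# a disordered-like charge/proline-rich sequence. Used only to centre the
# logistic so the pair straddles 0.5 under a given potential.
CALIBRATION_ORDERED <-
  "LVIFAGLWVALIGFMAVLCMVAILFAYVLIGAFLVWMAVILGFA"
CALIBRATION_DISORDERED <-
  "EDSPKEEGKRPSDDQEEGKRPSEDKPGSEEDKRPSQEDSPKEGR"

#' Boltzmann-inverted pairwise interaction potential
#'
#' Pairing frequencies rho_ij count ordered co-occurrences of residues i and
#' j within `contact_window` positions along the chain, across the corpus;
#' the reference rho*_ij is the product of marginal frequencies. The energy
#' is `E_ij = -ln(rho_ij / rho*_ij)`; cells never observed are left `NA`
#' (flagged, not fabricated) and imputed only at scoring time.
#'
#' @param corpus a `ResidueSequence` or list of them.
#' @param contact_window maximum sequence separation counted as a contact
#'   (>= 1).
#' @return object of class `PairPotential`: 20 x 20 `energies`, `observed`
#'   (rho), `reference` (rho*) and `contact_window`.
#' @export
estimate_pair_potential <- function(corpus, contact_window = 2) {
  if (inherits(corpus, "ResidueSequence")) corpus <- list(corpus)
  if (length(corpus) == 0) stop("empty corpus")
  if (contact_window < 1) stop("contact_window must be >= 1")
  counts <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  total_res <- 0
  for (s in corpus) {
    letters <- seq_letters(s)
    letters <- letters[letters %in% AA_ALPHABET]
    total_res <- total_res + length(letters)
    n <- length(letters)
    for (d in seq_len(min(contact_window, max(0, n - 1)))) {
      a <- letters[seq_len(n - d)]
      b <- letters[seq_len(n - d) + d]
      for (k in seq_along(a)) {
        counts[a[k], b[k]] <- counts[a[k], b[k]] + 1
        counts[b[k], a[k]] <- counts[b[k], a[k]] + 1
      }
    }
  }
  if (total_res < 2) stop("corpus must contain at least 2 residues")
  total <- sum(counts)
  if (total == 0) stop("no residue pairs within the contact window")
  rho <- counts / total
  marg <- rowSums(rho)
  rho_star <- outer(marg, marg)
  energies <- matrix(NA_real_, 20, 20,
                     dimnames = list(AA_ALPHABET, AA_ALPHABET))
  pos <- rho > 0 & rho_star > 0
  energies[pos] <- -log(rho[pos] / rho_star[pos])
  structure(list(energies = energies, observed = rho, reference = rho_star,
                 contact_window = contact_window),
            class = "PairPotential")
}

#' Construct a PairPotential from an explicit energy matrix
#'
#' @param energies symmetric numeric matrix with amino-acid dimnames.
#' @return a `PairPotential` (observed/reference unset).
#' @export
pair_potential <- function(energies) {
  if (!is.matrix(energies) || is.null(rownames(energies))) {
    stop("energies must be a named square matrix")
  }
  if (!isTRUE(all.equal(energies, t(energies), tolerance = 1e-9,
                        check.attributes = FALSE))) {
    stop("energies must be symmetric")
  }
  structure(list(energies = energies, observed = NULL, reference = NULL,
                 contact_window = NA_integer_),
            class = "PairPotential")
}

# unseen pairings are treated as unfavourable: NA cells take row max + 1
imputed_energies <- function(potential) {
  e <- potential$energies
  for (i in seq_len(nrow(e))) {
    if (anyNA(e[i, ])) {
      mx <- suppressWarnings(max(e[i, ], na.rm = TRUE))
      if (!is.finite(mx)) mx <- 0
      e[i, is.na(e[i, ])] <- mx + 1
    }
  }
  e
}

window_energies <- function(letters, e, window) {
  n <- length(letters)
  half <- (window - 1) %/% 2
  idx <- match(letters, rownames(e))
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    nb <- setdiff(lo:hi, i)
    if (length(nb) == 0) return(0)
    mean(e[idx[i], idx[nb]])
  }, numeric(1))
}

#' Calibrate the logistic midpoint of the disorder scorer
#'
#' Midpoint halfway between the mean window energies of a packaged
#' ordered-like and disordered-like synthetic sequence pair, so the pair
#' straddles 0.5 under the given potential.
#'
#' @param potential a `PairPotential`.
#' @param window odd window size.
#' @return numeric midpoint.
#' @export
calibrate_midpoint <- function(potential, window = 21) {
  e <- imputed_energies(potential)
  pair <- c(CALIBRATION_ORDERED, CALIBRATION_DISORDERED)
  ok <- all(unlist(strsplit(pair, "")) %in% rownames(e))
  if (!ok) {
    # toy alphabets: centre on the composition-weighted mean energy
    return(mean(e))
  }
  means <- vapply(pair, function(s) {
    mean(window_energies(strsplit(s, "")[[1]], e, window))
  }, numeric(1))
  mean(means)
}

#' Per-residue disorder profile
#'
#' The estimated energy of residue i is the mean pair energy between its
#' amino acid and the residues inside a centred window (truncated at the
#' termini); the disorder score is `plogis((e_i - midpoint)/slope)`, an
#' increasing function of energy so favourable contacts lower the score.
#'
#' @param seq a [residue_sequence()].
#' @param potential a `PairPotential`.
#' @param window odd integer >= 3.
#' @param midpoint logistic midpoint; default calibrated via
#'   [calibrate_midpoint()].
#' @param slope logistic slope (> 0).
#' @return object of class `DisorderProfile` with per-residue `scores` in
#'   `[0, 1]`, the sequence `numbering` and the window used.
#' @export
disorder_profile <- function(seq, potential, window = 21, midpoint = NULL,
                             slope = 0.5) {
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  if (slope <= 0) stop("slope must be positive")
  letters <- seq_letters(seq)
  if (length(letters) == 0) stop("empty sequence")
  e <- imputed_energies(potential)
  missing <- setdiff(unique(letters), rownames(e))
  if (length(missing) > 0) {
    stop("potential lacks letters: ", paste(missing, collapse = ", "))
  }
  if (is.null(midpoint)) midpoint <- calibrate_midpoint(potential, window)
  energies <- window_energies(letters, e, window)
  scores <- stats::plogis((energies - midpoint) / slope)
  structure(list(scores = scores, numbering = seq$numbering, window = window,
                 id = seq$id),
            class = "DisorderProfile")
}

#' Read per-residue disorder scores from a TSV
#'
#' Two-column file (residue author number, score in `[0, 1]`), tab- or
#' whitespace-separated, `#` comments allowed. Lets externally computed
#' scores (e.g. published predictor output) feed the thermodynamic layer.
#'
#' @param path TSV file.
#' @param window nominal window recorded on the profile.
#' @return a `DisorderProfile`.
#' @export
read_disorder_scores <- function(path, window = 21) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stop("expected two columns (resno, score) in ", path)
  scores <- as.numeric(tab[[2]])
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1)) {
    stop("scores must lie in [0, 1]")
  }
  structure(list(scores = scores, numbering = as.integer(tab[[1]]),
                 window = window, id = basename(path)),
            class = "DisorderProfile")
}

#' Mean disorder score over an author-number span
#'
#' @param profile a `DisorderProfile`.
#' @param span length-2 author-number range (inclusive); default the whole
#'   profile.
#' @return arithmetic mean of the scores in the span.
#' @export
domain_mean <- function(profile, span = NULL) {
  if (is.null(span)) span <- range(profile$numbering)
  sel <- profile$numbering >= span[1] & profile$numbering <= span[2]
  if (!any(sel)) stop("span ", span[1], "-", span[2], " empty in profile")
  mean(profile$scores[sel])
}

#' Charge-hydrophobicity classification
#'
#' Computes the absolute mean net charge per residue and the min-max
#' normalised Kyte-Doolittle hydrophobicity (5-residue window average), and
#' classifies the point against the natively-unfolded boundary line
#' `<R> = 2.785 <H> - 1.151`: points above the line (high charge, low
#' hydrophobicity) fall on the disordered side.
#'
#' @param seq a [residue_sequence()].
#' @param charge_table named charges per amino acid (default D/E = -1,
#'   K/R = +1, H = +0.1).
#' @param window hydropathy smoothing window.
#' @return object of class `ChargeHydroPoint`: `mean_net_charge`,
#'   `mean_hydrophobicity`, `classification`.
#' @export
charge_hydrophobicity <- function(seq, charge_table = default_charge_table(),
                                  window = 5) {
  letters <- seq_letters(seq)
  if (length(letters) == 0) stop("empty sequence")
  q <- charge_table[letters]
  q[is.na(q)] <- 0
  mnc <- abs(mean(q))
  kd <- KYTE_DOOLITTLE[letters]
  kd[is.na(kd)] <- 0
  h <- (kd + 4.5) / 9
  half <- (window - 1) %/% 2
  n <- length(h)
  h_smooth <- vapply(seq_len(n), function(i) {
    mean(h[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  mh <- mean(h_smooth)
  boundary <- 2.785 * mh - 1.151
  structure(list(mean_net_charge = mnc, mean_hydrophobicity = mh,
                 classification = if (mnc > boundary) "disordered-side"
                                  else "ordered-side"),
            class = "ChargeHydroPoint")
}
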