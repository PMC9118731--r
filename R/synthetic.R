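# Synthetic fixtures: idealized ankyrin structures, complexes with planted
# hydrogen bonds, charge-cluster models and qPCR curves
#
# Every generator is seed-deterministic and its planted truth (charges,
# bonds, patches, efficiencies) is recoverable exactly in the noiseless
# case, so these outputs double as oracles for the analysis modules.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

ideal_helix_ca <- function(n, origin, direction = c(0, 0, 1),
                           radius = 2.3, rise = 1.5, turn = 100) {
  t <- seq_len(n) - 1
  theta <- turn * pi / 180 * t
  # local frame: axis along `direction`
  w <- direction / sqrt(sum(direction^2))
  u <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- u - sum(u * w) * w; u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  t(vapply(seq_len(n), function(i) {
    origin + radius * cos(theta[i]) * u + radius * sin(theta[i]) * v +
      rise * t[i] * w
  }, numeric(3)))
}

backbone_atoms <- function(ca, resid, resno, chain) {
  rbind(
    data.frame(chain = chain, resno = resno, ins = "", resid = resid,
               elety = "N", elesy = "N",
               x = ca[1] - 1.0, y = ca[2] + 0.6, z = ca[3] - 0.8, occ = 1),
    data.frame(chain = chain, resno = resno, ins = "", resid = resid,
               elety = "CA", elesy = "C",
               x = ca[1], y = ca[2], z = ca[3], occ = 1),
    data.frame(chain = chain, resno = resno, ins = "", resid = resid,
               elety = "C", elesy = "C",
               x = ca[1] + 1.0, y = ca[2] + 0.5, z = ca[3] + 0.8, occ = 1),
    data.frame(chain = chain, resno = resno, ins = "", resid = resid,
               elety = "O", elesy = "O",
               x = ca[1] + 1.6, y = ca[2] + 1.5, z = ca[3] + 1.0, occ = 1)
  )
}

sidechain_atoms <- function(ca, letter, resno, chain, out_dir) {
  resid <- names(AA_321)[AA_321 == letter]
  out <- out_dir / sqrt(sum(out_dir^2))
  perp <- c(-out[2], out[1], 0)
  if (sum(perp^2) < 1e-9) perp <- c(1, 0, 0)
  perp <- perp / sqrt(sum(perp^2))
  site <- function(elety, elesy, pos) {
    data.frame(chain = chain, resno = resno, ins = "", resid = resid,
               elety = elety, elesy = elesy,
               x = pos[1], y = pos[2], z = pos[3], occ = 1)
  }
  if (letter == "D") {
    rbind(site("OD1", "O", ca + 2.4 * out + 1.1 * perp),
          site("OD2", "O", ca + 2.4 * out - 1.1 * perp))
  } else if (letter == "E") {
    rbind(site("OE1", "O", ca + 3.2 * out + 1.1 * perp),
          site("OE2", "O", ca + 3.2 * out - 1.1 * perp))
  } else if (letter == "K") {
    site("NZ", "N", ca + 3.6 * out)
  } else if (letter == "R") {
    site("CZ", "C", ca + 3.4 * out)
  } else NULL
}

#' Idealized multi-repeat ankyrin structure
#'
#' Builds `n_repeats` stacked 33-residue repeats with ideal helix geometry
#' (1.5 A rise, 100 degree turn) for the two helices (template positions
#' 5-12 and 15-24, the second antiparallel), an out-and-back hairpin
#' (25-31) and straight connecting loops. Backbone N/CA/C/O atoms are laid
#' down for every residue and minimal charged side chains (carboxyl oxygen
#' pairs, NZ, CZ) wherever the sequence has D/E/K/R.
#'
#' @param n_repeats number of repeats (0 gives an empty model).
#' @param sequence amino-acid string of length `33 * n_repeats`; default
#'   repeats the first packaged consensus repeat.
#' @param start_number author number of the first residue.
#' @param chain_id chain identifier.
#' @param repeat_spacing stacking distance between repeats along the domain
#'   long axis (A).
#' @return a [structure_model()].
#' @export
make_repeat_structure <- function(n_repeats, sequence = NULL,
                                  start_number = 1, chain_id = "A",
                                  repeat_spacing = 10) {
  if (n_repeats == 0) {
    return(structure_model(
      data.frame(chain = character(), resno = integer(), ins = character(),
                 resid = character(), elety = character(),
                 elesy = character(), x = numeric(), y = numeric(),
                 z = numeric(), occ = numeric()),
      source_id = "synthetic_ank"))
  }
  w <- ANK_REPEAT_LENGTH
  if (is.null(sequence)) {
    sequence <- paste(rep(ANK_REPEAT_SET[1], n_repeats), collapse = "")
  }
  sequence <- toupper(sequence)
  if (nchar(sequence) != w * n_repeats) {
    stop("sequence length ", nchar(sequence), " != 33 * ", n_repeats)
  }
  letters <- strsplit(sequence, "")[[1]]
  rows <- list()
  for (r in seq_len(n_repeats) - 1) {
    y0 <- r * repeat_spacing
    ca <- matrix(NA_real_, w, 3)
    ca[5:12, ] <- ideal_helix_ca(8, origin = c(0, y0, 0))
    ca[15:24, ] <- ideal_helix_ca(10, origin = c(9, y0, 13.5),
                                  direction = c(0, 0, -1))
    # hairpin: strand out (+x), 4-residue turn apex, strand back
    ca[25, ] <- c(12.0, y0 - 1.0, -1.0)
    ca[26, ] <- c(15.3, y0 - 1.0, -1.0)
    ca[27, ] <- c(18.6, y0 - 1.0, -1.0)
    ca[28, ] <- c(20.6, y0 + 0.5, 0.0)
    ca[29, ] <- c(18.6, y0 + 2.0, 1.0)
    ca[30, ] <- c(15.3, y0 + 2.0, 1.0)
    ca[31, ] <- c(12.0, y0 + 2.0, 1.0)
    # straight loops: 1-4 leading into a1, 13-14 linker, 32-33 exit
    lead_from <- c(-9, y0 - 3, -3)
    for (k in 1:4) ca[k, ] <- lead_from + (k / 5) * (ca[5, ] - lead_from)
    for (k in 13:14) ca[k, ] <- ca[12, ] + ((k - 12) / 3) * (ca[15, ] - ca[12, ])
    for (k in 32:33) ca[k, ] <- ca[31, ] + (k - 31) * c(-3, 1.5, -1)
    centre <- colMeans(ca[c(5:12, 15:24), ])
    for (k in seq_len(w)) {
      i_global <- r * w + k
      resno <- start_number + i_global - 1
      letter <- letters[i_global]
      resid <- names(AA_321)[AA_321 == letter]
      if (length(resid) == 0) resid <- "UNK"
      bb <- backbone_atoms(ca[k, ], resid, resno, chain_id)
      rows[[length(rows) + 1]] <- bb
      out_dir <- ca[k, ] - centre
      out_dir[2] <- 0  # push side chains outward in the helix plane
      if (sum(out_dir^2) < 1e-9) out_dir <- c(1, 0, 0)
      sc <- sidechain_atoms(ca[k, ], letter, resno, chain_id, out_dir)
      if (!is.null(sc)) rows[[length(rows) + 1]] <- sc
    }
  }
  structure_model(do.call(rbind, rows), source_id = "synthetic_ank")
}

#' Multi-chain complex with planted hydrogen bonds
#'
#' Each planted bond is realized as a glycine donor (backbone N with its CA
#' antecedent) on one chain and a glycine acceptor (backbone C=O) on
#' another, at the prescribed donor-acceptor distance and
#' antecedent-donor-acceptor angle. Bonds are laid out on a coarse spatial
#' grid so no unplanted polar contact forms; several bonds may share one
#' donor residue (bifurcated geometry). Every declared chain receives a
#' distant CA-only anchor residue so it exists even with no bonds.
#'
#' @param chains character vector of chain ids.
#' @param bonds data.frame with columns `donor_chain`, `donor_resno`,
#'   `acc_chain`, `acc_resno` and optionally `distance` (default 2.9) and
#'   `angle` (default 160).
#' @return a [structure_model()].
#' @export
make_planted_complex <- function(chains, bonds = NULL) {
  if (length(chains) < 1) stop("need at least one chain")
  rows <- list()
  glycine <- function(chain, resno, elety, elesy, pos) {
    data.frame(chain = chain, resno = resno, ins = "", resid = "GLY",
               elety = elety, elesy = elesy,
               x = pos[1], y = pos[2], z = pos[3], occ = 1)
  }
  for (k in seq_along(chains)) {
    rows[[length(rows) + 1]] <-
      glycine(chains[k], 99990 + k, "CA", "C", c(500 + 50 * k, 500, 500))
  }
  if (!is.null(bonds) && nrow(bonds) > 0) {
    if (!all(c(bonds$donor_chain, bonds$acc_chain) %in% chains)) {
      stop("bond references a chain not in `chains`")
    }
    if (is.null(bonds$distance)) bonds$distance <- 2.9
    if (is.null(bonds$angle)) bonds$angle <- 160
    if (any(bonds$distance <= 1.6)) stop("planted distance too short")
    donor_key <- paste(bonds$donor_chain, bonds$donor_resno)
    donors <- unique(donor_key)
    placed_donor <- list()
    n_acc_at_donor <- stats::setNames(integer(length(donors)), donors)
    for (b in seq_len(nrow(bonds))) {
      dk <- donor_key[b]
      slot <- match(dk, donors) - 1
      origin <- c(30 * (slot %% 10), 30 * (slot %/% 10), 0)
      if (is.null(placed_donor[[dk]])) {
        rows[[length(rows) + 1]] <-
          glycine(bonds$donor_chain[b], bonds$donor_resno[b], "N", "N",
                  origin)
        rows[[length(rows) + 1]] <-
          glycine(bonds$donor_chain[b], bonds$donor_resno[b], "CA", "C",
                  origin + c(-1.45, 0, 0))
        placed_donor[[dk]] <- origin
      }
      # acceptor direction: in-plane angle `angle` from the CA->N direction,
      # successive acceptors fanned about the x-axis
      theta <- (180 - bonds$angle[b]) * pi / 180
      rot <- n_acc_at_donor[[dk]] * 40 * pi / 180
      n_acc_at_donor[[dk]] <- n_acc_at_donor[[dk]] + 1
      v <- c(cos(theta), sin(theta) * cos(rot), sin(theta) * sin(rot))
      o_pos <- origin + bonds$distance[b] * v
      c_pos <- o_pos + bonds$distance[b] * 0.42 * v  # carbonyl C behind the O
      rows[[length(rows) + 1]] <-
        glycine(bonds$acc_chain[b], bonds$acc_resno[b], "O", "O", o_pos)
      rows[[length(rows) + 1]] <-
        glycine(bonds$acc_chain[b], bonds$acc_resno[b], "C", "C", c_pos)
    }
  }
  structure_model(do.call(rbind, rows), source_id = "synthetic_complex")
}

#' Charge-cluster fixture with known patch membership
#'
#' Places clusters of aspartate (negative) or lysine (positive) residues,
#' each cluster tight around its centre, with centres mutually farther apart
#' than `min_separation` (default three Debye lengths at 0.15 M). The
#' expected patch membership is the residue set of each cluster.
#'
#' @param clusters list of `list(center = c(x, y, z), n_charges, sign)` with
#'   sign `-1` or `+1`.
#' @param min_separation minimum centre-centre distance (A).
#' @return list with `model` (a [structure_model()]) and `expected` (list of
#'   residue-id vectors, one per cluster, as in `ChargedPatch`
#'   `member_residues`).
#' @export
make_charge_fixture <- function(clusters,
                                min_separation = 3 * debye_length(0.15)) {
  if (length(clusters) >= 2) {
    centres <- t(vapply(clusters, function(cl) cl$center, numeric(3)))
    d <- stats::dist(centres)
    if (any(d < min_separation)) {
      stop("cluster centres closer than the minimum separation (",
           signif(min_separation, 3), " A)")
    }
  }
  rows <- list()
  expected <- list()
  resno <- 0
  for (cl in clusters) {
    ids <- character(0)
    for (k in seq_len(cl$n_charges)) {
      resno <- resno + 1
      ca <- cl$center + c(2.6 * (k - (cl$n_charges + 1) / 2), 0, -2.4)
      resid <- if (cl$sign < 0) "ASP" else "LYS"
      rows[[length(rows) + 1]] <- data.frame(
        chain = "A", resno = resno, ins = "", resid = resid,
        elety = "CA", elesy = "C", x = ca[1], y = ca[2], z = ca[3], occ = 1)
      if (cl$sign < 0) {
        rows[[length(rows) + 1]] <- data.frame(
          chain = "A", resno = resno, ins = "", resid = resid,
          elety = c("OD1", "OD2"), elesy = "O",
          x = ca[1] + c(-1.1, 1.1), y = ca[2], z = ca[3] + 2.4, occ = 1)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          chain = "A", resno = resno, ins = "", resid = resid,
          elety = "NZ", elesy = "N",
          x = ca[1], y = ca[2], z = ca[3] + 2.4, occ = 1)
      }
      ids <- c(ids, paste0("A:", resid, "-", resno))
    }
    expected[[length(expected) + 1]] <- ids
  }
  list(model = structure_model(do.call(rbind, rows),
                               source_id = "synthetic_charges"),
       expected = expected)
}

#' Simulated qPCR amplification curve
#'
#' `fluorescence = baseline + amplitude * efficiency^cycle * (1 + noise)`,
#' capped at the plateau level reached at `plateau_cycle`; noise is Gaussian
#' with relative standard deviation `noise_sd`, seed-deterministic.
#'
#' @param efficiency true fold-per-cycle efficiency (1 < eff <= 2).
#' @param cycles number of cycles.
#' @param amplitude pre-exponential scale.
#' @param baseline additive background.
#' @param noise_sd relative noise standard deviation (>= 0).
#' @param plateau_cycle cycle at which the signal saturates.
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @return data.frame with `cycle` and `fluorescence`.
#' @export
make_qpcr_curve <- function(efficiency, cycles = 30, amplitude = 1e-6,
                            baseline = 0, noise_sd = 0, plateau_cycle = 26,
                            seed = NULL) {
  if (efficiency <= 1 || efficiency > 2) stop("efficiency must be in (1, 2]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  cyc <- seq_len(cycles)
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(cycles, 0, noise_sd))
  } else rep(0, cycles)
  f <- baseline + amplitude * efficiency^cyc * (1 + noise)
  cap <- baseline + amplitude * efficiency^plateau_cycle
  data.frame(cycle = cyc, fluorescence = pmin(f, cap))
}
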