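# Geometric hydrogen-bond detection and interface inventories
#
# A hydrogen bond is called between a donor heavy atom (N/O/S bearing a
# hydrogen) and an acceptor heavy atom when their distance is at most d_max
# and the geometry is compatible: with an explicit hydrogen on the donor the
# donor-H...acceptor angle must reach angle_min; otherwise the
# antecedent-donor-acceptor angle (the angle at the donor between its bonded
# antecedent and the acceptor) is used. Criteria are configurable; defaults
# are the standard 3.5 A / 120 degrees.

# donor atoms and their covalent antecedents, by residue type
DONOR_TABLE <- list(
  ALL = list(N = "CA"),                      # backbone amide
  SER = list(OG = "CB"), THR = list(OG1 = "CB"), TYR = list(OH = "CZ"),
  CYS = list(SG = "CB"), LYS = list(NZ = "CE"),
  ARG = list(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  HIS = list(ND1 = "CG", NE2 = "CD2"),
  ASN = list(ND2 = "CG"), GLN = list(NE2 = "CD"), TRP = list(NE1 = "CD1")
)

ACCEPTOR_TABLE <- list(
  ALL = c("O", "OXT"),                       # backbone carbonyl
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH",
  HIS = c("ND1", "NE2"), MET = "SD"
)

res_key <- function(a) paste(a$chain, a$resno, a$ins, sep = "\r")

# donor candidates with antecedent coordinates; falls back to "nearest heavy
# atom in the same residue" for residues outside the table (synthetic
# minimal models)
collect_donors <- function(atoms) {
  out <- list()
  key <- res_key(atoms)
  for (i in seq_len(nrow(atoms))) {
    ele <- toupper(atoms$elesy[i])
    if (!ele %in% c("N", "O", "S")) next
    resid <- atoms$resid[i]
    tab <- c(DONOR_TABLE[[resid]], DONOR_TABLE$ALL)
    ante_name <- tab[[atoms$elety[i]]]
    known <- !is.null(ante_name)
    if (!known && resid %in% names(AA_321)) next  # standard residue, not a donor atom
    same <- which(key == key[i])
    same <- setdiff(same, i)
    ante <- NULL
    if (known) {
      j <- same[atoms$elety[same] == ante_name]
      if (length(j) >= 1) ante <- j[1]
    }
    if (is.null(ante) && length(same) > 0) {
      dd <- (atoms$x[same] - atoms$x[i])^2 + (atoms$y[same] - atoms$y[i])^2 +
        (atoms$z[same] - atoms$z[i])^2
      if (min(dd) < 4) ante <- same[which.min(dd)]
    }
    if (!known && toupper(atoms$elesy[i]) == "O") {
      # generic O: only treat hydroxyl-like O (single antecedent) as donor
      if (is.null(ante)) next
    }
    out[[length(out) + 1]] <- list(idx = i, ante = ante)
  }
  out
}

collect_acceptors <- function(atoms) {
  idx <- integer(0)
  for (i in seq_len(nrow(atoms))) {
    ele <- toupper(atoms$elesy[i])
    if (!ele %in% c("N", "O", "S")) next
    resid <- atoms$resid[i]
    acc <- c(ACCEPTOR_TABLE[[resid]], ACCEPTOR_TABLE$ALL)
    known_res <- resid %in% names(AA_321)
    if (known_res && !atoms$elety[i] %in% acc) next
    if (!known_res && ele == "N") next  # generic N treated as donor only
    idx <- c(idx, i)
  }
  idx
}

angle_deg <- function(p1, p2, p3) {
  # angle at p2
  u <- p1 - p2; v <- p3 - p2
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect hydrogen bonds in a structure
#'
#' @param model a `StructureModel`.
#' @param d_max maximum donor-acceptor heavy-atom distance (Angstrom).
#' @param angle_min minimum angle (degrees): donor-H...acceptor when a
#'   hydrogen is bonded to the donor, otherwise antecedent-donor-acceptor.
#'   Donors without a resolvable antecedent pass on distance alone.
#' @return data.frame of bonds: donor/acceptor chain, residue number,
#'   residue name and atom name, `distance` and `angle` (NA when no
#'   geometry reference was available), one row per donor-acceptor pair.
#' @export
detect_hbonds <- function(model, d_max = 3.5, angle_min = 120) {
  atoms <- model$atoms
  donors <- collect_donors(atoms)
  acceptors <- collect_acceptors(atoms)
  key <- res_key(atoms)
  hyd <- which(toupper(atoms$elesy) == "H")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  rows <- list()
  for (d in donors) {
    i <- d$idx
    dd <- sqrt(colSums((t(coords[acceptors, , drop = FALSE]) - coords[i, ])^2))
    cand <- acceptors[dd <= d_max & key[acceptors] != key[i]]
    dist_cand <- dd[dd <= d_max & key[acceptors] != key[i]]
    if (length(cand) == 0) next
    # hydrogens covalently bonded to this donor, if the model has any
    dh <- hyd[key[hyd] == key[i]]
    if (length(dh) > 0) {
      hd <- sqrt(colSums((t(coords[dh, , drop = FALSE]) - coords[i, ])^2))
      dh <- dh[hd <= 1.25]
    }
    for (k in seq_along(cand)) {
      j <- cand[k]
      ang <- NA_real_
      ok <- TRUE
      if (length(dh) > 0) {
        angs <- vapply(dh, function(h) {
          angle_deg(coords[i, ], coords[h, ], coords[j, ])
        }, numeric(1))
        ang <- max(angs)
        ok <- ang >= angle_min
      } else if (!is.null(d$ante)) {
        ang <- angle_deg(coords[d$ante, ], coords[i, ], coords[j, ])
        ok <- ang >= angle_min
      }
      if (!ok) next
      rows[[length(rows) + 1]] <- data.frame(
        donor_chain = atoms$chain[i], donor_resno = atoms$resno[i],
        donor_resid = atoms$resid[i], donor_atom = atoms$elety[i],
        acc_chain = atoms$chain[j], acc_resno = atoms$resno[j],
        acc_resid = atoms$resid[j], acc_atom = atoms$elety[j],
        distance = dist_cand[k], angle = ang)
    }
  }
  # each donor-acceptor atom pair is visited exactly once, so rows are
  # already unique (bifurcated bonds stay individual)
  bonds <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(donor_chain = character(), donor_resno = integer(),
               donor_resid = character(), donor_atom = character(),
               acc_chain = character(), acc_resno = integer(),
               acc_resid = character(), acc_atom = character(),
               distance = numeric(), angle = numeric())
  rownames(bonds) <- NULL
  bonds
}

#' Inter-group hydrogen-bond inventory
#'
#' Restricts [detect_hbonds()] to pairs whose donor and acceptor chains fall
#' in different named groups (e.g. ANK / MAML1 / RBPJ of the ternary
#' transcription complex) and counts bonds per unordered group pair.
#'
#' @param model a `StructureModel`.
#' @param groups named list mapping group name to chain id(s); must cover at
#'   least two chains, and every chain named must exist in the model.
#' @param d_max,angle_min geometric criteria, see [detect_hbonds()].
#' @return object of class `InterfaceInventory`: `bonds` (data.frame with a
#'   `pair` column `"A|B"`, names sorted), `counts` (named integer vector),
#'   and the criteria used.
#' @export
interface_inventory <- function(model, groups, d_max = 3.5, angle_min = 120) {
  chains <- model_chains(model)
  all_gchains <- unlist(groups)
  unknown <- setdiff(all_gchains, chains)
  if (length(unknown) > 0) {
    stop("groups name chain(s) absent from model: ",
         paste(unknown, collapse = ", "))
  }
  chain2group <- stats::setNames(
    rep(names(groups), lengths(groups)), all_gchains)
  bonds <- detect_hbonds(model, d_max, angle_min)
  gd <- chain2group[bonds$donor_chain]
  ga <- chain2group[bonds$acc_chain]
  keep <- !is.na(gd) & !is.na(ga) & gd != ga
  bonds <- bonds[keep, , drop = FALSE]
  gd <- gd[keep]; ga <- ga[keep]
  pair <- vapply(seq_along(gd), function(i) {
    paste(sort(c(gd[i], ga[i])), collapse = "|")
  }, character(1))
  bonds$pair <- if (nrow(bonds) > 0) pair else character(0)
  rownames(bonds) <- NULL
  counts <- table(factor(bonds$pair))
  structure(list(bonds = bonds,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 d_max = d_max, angle_min = angle_min),
            class = "InterfaceInventory")
}

#' @export
print.InterfaceInventory <- function(x, ...) {
  cat("InterfaceInventory (d_max", x$d_max, "A, angle_min", x$angle_min,
      "deg)\n")
  if (length(x$counts) == 0) cat("  no inter-group hydrogen bonds\n")
  for (p in names(x$counts)) cat("  ", p, ":", x$counts[[p]], "bond(s)\n")
  invisible(x)
}

#' Bonds of a group pair that involve given residues
#'
#' @param inventory an `InterfaceInventory`.
#' @param pair unordered group pair as `c("ANK", "MAML1")`.
#' @param resno author residue numbers; a bond matches when its donor or
#'   acceptor residue number is in the set (on either side).
#' @return the matching rows of the bond table.
#' @export
interface_bonds_involving <- function(inventory, pair, resno) {
  key <- paste(sort(pair), collapse = "|")
  b <- inventory$bonds[inventory$bonds$pair == key, , drop = FALSE]
  b[b$donor_resno %in% resno | b$acc_resno %in% resno, , drop = FALSE]
}
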