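# Surface electrostatics: formal charges, dot surface, screened-Coulomb
# potential, charged-zone detection and acidic-residue geometry
#
# The potential is single-dielectric Debye-Hueckel screening
# phi(r) = sum_i C q_i exp(-|r - r_i| / lambda_D) / (eps |r - r_i|), with C
# the Coulomb constant in kJ.A.mol^-1.e^-2 and lambda_D from the ionic
# strength and temperature. Patch areas under this stand-in are comparative
# quantities; zone identity (which residues line a zone) is the robust
# readout.

# e^2 * N_A / (4 pi eps0), in kJ.A/mol
COULOMB_KJ_A_MOL <- {
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12; na <- 6.02214076e23
  e^2 * na / (4 * pi * eps0) * 1e10 / 1000
}

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
               SE = 1.90)

atom_radii <- function(elesy) {
  r <- VDW_RADII[toupper(elesy)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Debye screening length
#'
#' @param ionic_strength mol/L of monovalent salt (>= 0).
#' @param eps relative solvent dielectric.
#' @param temperature K.
#' @return length in Angstrom; `Inf` at zero ionic strength (pure Coulomb).
#' @export
debye_length <- function(ionic_strength = 0.15, eps = 78,
                         temperature = 298.15) {
  if (ionic_strength < 0) stop("ionic_strength must be >= 0")
  if (ionic_strength == 0) return(Inf)
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12
  kb <- 1.380649e-23; na <- 6.02214076e23
  kappa2 <- 2 * na * e^2 * ionic_strength * 1000 / (eps0 * eps * kb * temperature)
  1e10 / sqrt(kappa2)
}

CHARGE_SITES <- list(
  ASP = list(atoms = c("OD1", "OD2"), q = -1),
  GLU = list(atoms = c("OE1", "OE2"), q = -1),
  LYS = list(atoms = "NZ", q = +1),
  ARG = list(atoms = "CZ", q = +1),
  HIS = list(atoms = c("ND1", "NE2"), q = NA)  # q from his_charge
)

#' Assign formal side-chain charges
#'
#' Aspartate/glutamate contribute -1 at the carboxyl-oxygen midpoint, lysine
#' +1 at NZ, arginine +1 at CZ; histidine takes `his_charge` (default 0, the
#' pH 7 approximation) at the imidazole-nitrogen midpoint. Residues whose
#' charge-bearing atoms are missing are skipped with a warning.
#'
#' @param model a `StructureModel`.
#' @param his_charge histidine charge in e.
#' @return object of class `ChargeModel`: data.frame with `chain`, `resno`,
#'   `ins`, `resid`, site coordinates `x`, `y`, `z` and `q` (e).
#' @export
assign_charges <- function(model, his_charge = 0) {
  a <- model$atoms
  rows <- list()
  skipped <- character(0)
  res <- unique(a[a$resid %in% names(CHARGE_SITES),
                  c("chain", "resno", "ins", "resid")])
  for (i in seq_len(nrow(res))) {
    spec <- CHARGE_SITES[[res$resid[i]]]
    q <- if (res$resid[i] == "HIS") his_charge else spec$q
    if (q == 0) next
    sel <- a$chain == res$chain[i] & a$resno == res$resno[i] &
      a$ins == res$ins[i] & a$elety %in% spec$atoms
    if (sum(sel) < length(spec$atoms)) {
      skipped <- c(skipped, paste0(res$resid[i], "-", res$resno[i]))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      chain = res$chain[i], resno = res$resno[i], ins = res$ins[i],
      resid = res$resid[i],
      x = mean(a$x[sel]), y = mean(a$y[sel]), z = mean(a$z[sel]), q = q)
  }
  if (length(skipped) > 0) {
    warning("skipped residues with missing charge sites: ",
            paste(skipped, collapse = ", "))
  }
  charges <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(chain = character(), resno = integer(), ins = character(),
               resid = character(), x = numeric(), y = numeric(),
               z = numeric(), q = numeric())
  rownames(charges) <- NULL
  class(charges) <- c("ChargeModel", "data.frame")
  charges
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Sample the solvent-accessible surface with a dot surface
#'
#' Shrake-Rupley style: dots are distributed on each atom's solvent-expanded
#' sphere (radius + probe) and retained when not occluded by any neighbour's
#' expanded sphere. Each retained dot carries an equal share of its atom's
#' expanded-sphere area.
#'
#' @param model a `StructureModel` with at least one atom.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param dots_per_atom dots on each atomic sphere.
#' @return data.frame of surface points: `x`, `y`, `z`, `area` (A^2),
#'   `atom`, `chain`, `resno`, `resid`.
#' @export
sample_surface <- function(model, probe = 1.4, dots_per_atom = 240) {
  a <- model$atoms
  n <- nrow(a)
  if (n == 0) stop("model has no atoms")
  radii <- atom_radii(a$elesy) + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  dirs <- fibonacci_sphere(dots_per_atom)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    pts <- sweep(dirs * radii[i], 2, xyz[i, ], "+")
    # neighbours whose expanded sphere can occlude dots of atom i
    dd <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(dd < radii + radii[i] & seq_len(n) != i)
    keep <- rep(TRUE, dots_per_atom)
    for (j in nb) {
      dj2 <- colSums((t(pts) - xyz[j, ])^2)
      keep <- keep & dj2 > radii[j]^2
    }
    if (any(keep)) {
      out[[i]] <- data.frame(
        x = pts[keep, 1], y = pts[keep, 2], z = pts[keep, 3],
        area = 4 * pi * radii[i]^2 / dots_per_atom,
        atom = i, chain = a$chain[i], resno = a$resno[i], resid = a$resid[i])
    }
  }
  pts <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(pts)) {
    pts <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      area = numeric(), atom = integer(), chain = character(),
                      resno = integer(), resid = character())
  }
  rownames(pts) <- NULL
  pts
}

#' Screened-Coulomb potential on surface points
#'
#' @param charges a `ChargeModel` from [assign_charges()].
#' @param points surface points from [sample_surface()] (or any data.frame
#'   with `x`, `y`, `z`).
#' @param ionic_strength mol/L monovalent salt; 0 gives the unscreened
#'   Coulomb potential.
#' @param eps solvent dielectric (default 78).
#' @param temperature K (default 298.15).
#' @return object of class `SurfacePotentialMap`: the points with a
#'   `potential` column (kJ·mol⁻¹·e⁻¹) plus the run parameters. Points
#'   coincident with a charge site (< 1e-6 A) are dropped with a warning.
#' @export
screened_potential <- function(charges, points, ionic_strength = 0.15,
                               eps = 78, temperature = 298.15) {
  if (eps <= 0) stop("eps must be positive")
  lambda <- debye_length(ionic_strength, eps, temperature)
  pot <- numeric(nrow(points))
  drop <- rep(FALSE, nrow(points))
  if (nrow(charges) > 0 && nrow(points) > 0) {
    px <- as.matrix(points[, c("x", "y", "z")])
    for (k in seq_len(nrow(charges))) {
      d <- sqrt((px[, 1] - charges$x[k])^2 + (px[, 2] - charges$y[k])^2 +
                  (px[, 3] - charges$z[k])^2)
      coincident <- d < 1e-6
      drop <- drop | coincident
      d[coincident] <- NA
      decay <- if (is.finite(lambda)) exp(-d / lambda) else 1
      pot <- pot + COULOMB_KJ_A_MOL * charges$q[k] * decay / (eps * d)
    }
  }
  if (any(drop)) {
    warning(sum(drop), " surface point(s) coincident with a charge excluded")
    points <- points[!drop, , drop = FALSE]
    pot <- pot[!drop]
  }
  points$potential <- if (nrow(points) > 0) pot else numeric(0)
  structure(list(points = points, ionic_strength = ionic_strength,
                 eps = eps, temperature = temperature,
                 debye_length = lambda),
            class = "SurfacePotentialMap")
}

#' Detect contiguous charged surface zones
#'
#' Points beyond the threshold (below it for negative patches, above for
#' positive) are linked when closer than the adjacency radius; connected
#' components are returned as patches, sorted by area, each reporting the
#' residues whose atoms own its points.
#'
#' @param map a `SurfacePotentialMap`.
#' @param threshold potential threshold in kJ·mol⁻¹·e⁻¹ (default -5, the
#'   extreme of the usual display scale).
#' @param sign `"neg"` or `"pos"`; must be consistent with the threshold
#'   sign.
#' @param adjacency linking distance in Angstrom; default twice the mean dot
#'   spacing, estimated as `sqrt(mean(area))`.
#' @return list of `ChargedPatch` objects: `member_points` (row indices into
#'   `map$points`), `area` (A^2), `mean_potential`, `sign`,
#'   `member_residues` (unique `chain:resno resid` ids).
#' @export
detect_patches <- function(map, threshold = -5, sign = c("neg", "pos"),
                           adjacency = NULL) {
  sign <- match.arg(sign)
  if (sign == "neg" && threshold > 0) stop("negative patches need threshold <= 0")
  if (sign == "pos" && threshold < 0) stop("positive patches need threshold >= 0")
  pts <- map$points
  sel <- if (sign == "neg") which(pts$potential <= threshold)
         else which(pts$potential >= threshold)
  if (length(sel) == 0) return(list())
  if (is.null(adjacency)) adjacency <- 2 * sqrt(mean(pts$area))
  sub <- pts[sel, , drop = FALSE]
  d <- as.matrix(stats::dist(sub[, c("x", "y", "z")]))
  adj <- d <= adjacency
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  patches <- lapply(seq_len(comp$no), function(k) {
    members <- sel[comp$membership == k]
    structure(
      list(member_points = members,
           area = sum(pts$area[members]),
           mean_potential = mean(pts$potential[members]),
           sign = sign,
           member_residues = unique(paste0(pts$chain[members], ":",
                                           pts$resid[members], "-",
                                           pts$resno[members]))),
      class = "ChargedPatch")
  })
  patches[order(vapply(patches, `[[`, numeric(1), "area"),
                decreasing = TRUE)]
}

#' @export
print.ChargedPatch <- function(x, ...) {
  cat(sprintf("ChargedPatch (%s): %.1f A^2, mean %.2f kJ/mol/e, %d point(s)\n",
              x$sign, x$area, x$mean_potential, length(x$member_points)))
  cat("  residues:", paste(x$member_residues, collapse = ", "), "\n")
  invisible(x)
}

parse_residue_id <- function(id) {
  m <- regmatches(id, regexec("^([A-Za-z]*)-?([0-9]+)$", id))[[1]]
  if (length(m) == 0) stop("cannot parse residue id: ", id)
  list(code = toupper(m[2]), resno = as.integer(m[3]))
}

carboxyl_midpoint <- function(model, chain, resno) {
  a <- model$atoms
  sel <- a$chain == chain & a$resno == resno
  if (!any(sel)) stop("residue ", resno, " not found in chain ", chain)
  resid <- a$resid[sel][1]
  if (!resid %in% c("ASP", "GLU")) {
    stop("residue ", resid, "-", resno, " is not aspartate/glutamate")
  }
  atoms <- if (resid == "ASP") c("OD1", "OD2") else c("OE1", "OE2")
  sel2 <- sel & a$elety %in% atoms
  if (sum(sel2) < 2) stop("carboxyl atoms missing for ", resid, "-", resno)
  c(mean(a$x[sel2]), mean(a$y[sel2]), mean(a$z[sel2]))
}

#' Pairwise distances between side-chain carboxyl midpoints
#'
#' @param model a `StructureModel`.
#' @param residues character ids like `"D1987"`, `"E2008"` or bare author
#'   numbers; each must be an aspartate or glutamate with intact carboxyl.
#' @param chain_id chain holding the residues (default: first chain).
#' @return symmetric matrix of Euclidean distances (Angstrom) with zero
#'   diagonal, dimnames the residue ids.
#' @export
carboxyl_distance_matrix <- function(model, residues,
                                     chain_id = model_chains(model)[1]) {
  mids <- t(vapply(residues, function(id) {
    carboxyl_midpoint(model, chain_id, parse_residue_id(id)$resno)
  }, numeric(3)))
  d <- as.matrix(stats::dist(mids))
  dimnames(d) <- list(residues, residues)
  d
}

#' Charge-distribution anisotropy
#'
#' Dipole-like first moment of the charge set about the unweighted centroid
#' of the charge sites.
#'
#' @param charges a `ChargeModel` with at least one charge.
#' @return list with `magnitude` (e·Angstrom) and `direction` (unit
#'   3-vector, zero vector when the magnitude is 0).
#' @export
charge_anisotropy <- function(charges) {
  if (nrow(charges) == 0) stop("no charges in model")
  r <- as.matrix(charges[, c("x", "y", "z")])
  centroid <- colMeans(r)
  m <- unname(colSums(charges$q * sweep(r, 2, centroid)))
  mag <- sqrt(sum(m^2))
  list(magnitude = mag,
       direction = if (mag > 1e-12) m / mag else c(0, 0, 0))
}
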