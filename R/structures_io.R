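# Structure and sequence I/O
#
# A StructureModel is a light container over an atom table in author (PDB)
# numbering: one row per atom with chain, resno, insertion code, residue
# name, atom name, element and coordinates. Author numbering is the only
# numbering ever exposed; downstream residue citations (ASP-1987, GLN-347,
# ...) are author numbers.

WATER_IONS <- c("HOH", "WAT", "DOD", "NA", "CL", "K", "MG", "CA", "ZN",
                "MN", "FE", "SO4", "PO4", "GOL", "EDO", "ACT")

#' Construct a StructureModel from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno` (integer author
#'   number), `ins` (insertion code, "" if none), `resid` (3-letter code),
#'   `elety` (atom name), `elesy` (element symbol), `x`, `y`, `z` (Angstrom)
#'   and `occ` (occupancy).
#' @param source_id accession or file name the model came from.
#' @param resolution resolution in Angstrom, or `NA` when unknown.
#' @return object of class `StructureModel`.
#' @export
structure_model <- function(atoms, source_id = "model", resolution = NA_real_) {
  required <- c("chain", "resno", "ins", "resid", "elety", "elesy",
                "x", "y", "z", "occ")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(atoms) > 0) {
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
      stop("non-finite atom coordinates")
    }
    ord <- order(match(atoms$chain, unique(atoms$chain)), atoms$resno,
                 atoms$ins)
    atoms <- atoms[ord, , drop = FALSE]
    rownames(atoms) <- NULL
  }
  structure(
    list(source_id = source_id, atoms = atoms, resolution = resolution),
    class = "StructureModel"
  )
}

#' @export
print.StructureModel <- function(x, ...) {
  ch <- model_chains(x)
  cat("StructureModel:", x$source_id, "\n")
  cat("  chains:", if (length(ch)) paste(ch, collapse = ", ") else "(none)",
      "\n")
  cat("  atoms:", nrow(x$atoms), " residues:",
      nrow(unique(x$atoms[c("chain", "resno", "ins")])), "\n")
  invisible(x)
}

#' Chain identifiers of a model
#' @param model a `StructureModel`.
#' @return character vector of chain ids in file order.
#' @export
model_chains <- function(model) unique(model$atoms$chain)

#' Residue table of one chain
#'
#' @param model a `StructureModel`.
#' @param chain_id chain identifier.
#' @return data.frame with one row per residue (`resno`, `ins`, `resid`),
#'   ordered by author number (insertion codes break ties but do not
#'   reorder).
#' @export
chain_residues <- function(model, chain_id) {
  sel <- model$atoms$chain == chain_id
  if (!any(sel)) stop("no such chain: ", chain_id)
  res <- unique(model$atoms[sel, c("resno", "ins", "resid")])
  res <- res[order(res$resno, res$ins), , drop = FALSE]
  rownames(res) <- NULL
  res
}

resolve_altloc <- function(atom) {
  if (nrow(atom) == 0 || !"alt" %in% names(atom)) return(atom)
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) {
    atom$alt <- NULL
    return(atom)
  }
  # one conformer per (chain, residue, atom name): highest occupancy wins,
  # ties broken by altloc label order ('' sorts before 'A')
  key <- paste(atom$chain, atom$resno, atom$ins, atom$elety, sep = "\r")
  occ <- atom$occ
  occ[is.na(occ)] <- 1
  ord <- order(key, -occ, alt)
  atom <- atom[ord, , drop = FALSE]
  atom <- atom[!duplicated(key[ord]), , drop = FALSE]
  atom$alt <- NULL
  atom[order(as.integer(rownames(atom))), , drop = FALSE]
}

#' Read a PDB file into a StructureModel
#'
#' ATOM and HETATM records of one model are parsed (via [bio3d::read.pdb]).
#' Alternate locations are reduced to a single conformer (highest occupancy,
#' then altloc label order). HETATM amino acids such as MSE are retained as
#' residues; waters and common ions/buffer molecules are dropped, as are
#' hetero groups without a CA atom.
#'
#' @param path PDB file.
#' @param model_index 1-based model number for multi-model files.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, model_index = 1) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("not parseable as PDB: ", path, " (",
                             conditionMessage(e), ")")
  )
  atom <- pdb$atom
  if (is.null(atom) || nrow(atom) == 0) stop("no ATOM records in ", path)
  n_models <- max(1L, nrow(pdb$xyz))
  if (model_index < 1 || model_index > n_models) {
    stop("model_index ", model_index, " out of range (file has ",
         n_models, " model(s))")
  }
  if (model_index > 1) {
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    atom$x <- xyz[, 1]; atom$y <- xyz[, 2]; atom$z <- xyz[, 3]
  }
  atoms <- data.frame(
    chain = ifelse(is.na(atom$chain), " ", atom$chain),
    resno = atom$resno,
    ins   = ifelse(is.na(atom$insert), "", atom$insert),
    resid = atom$resid,
    elety = atom$elety,
    elesy = ifelse(is.na(atom$elesy) | atom$elesy == "",
                   substr(gsub("[^A-Za-z].*", "", atom$elety), 1, 1),
                   atom$elesy),
    x = atom$x, y = atom$y, z = atom$z,
    occ = ifelse(is.na(atom$o), 1, atom$o),
    alt = ifelse(is.na(atom$alt), "", atom$alt),
    stringsAsFactors = FALSE
  )
  atoms <- atoms[!(atoms$resid %in% WATER_IONS), , drop = FALSE]
  atoms <- resolve_altloc(atoms)
  # drop hetero groups that are not residue-like (no CA atom and unknown code)
  key <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "\r")
  has_ca <- key %in% key[atoms$elety == "CA"]
  known <- atoms$resid %in% names(AA_321)
  atoms <- atoms[known | has_ca, , drop = FALSE]
  if (nrow(atoms) == 0) stop("no protein atoms in ", path)
  rownames(atoms) <- NULL
  res <- NA_real_
  if (!is.null(pdb$remark) && !is.null(pdb$remark$resolution)) {
    res <- suppressWarnings(as.numeric(pdb$remark$resolution))
    if (length(res) == 0) res <- NA_real_
  }
  structure_model(atoms, source_id = basename(path), resolution = res[1])
}

#' Write a StructureModel as PDB text
#'
#' Emits a minimal ATOM-record file sufficient to round-trip models produced
#' by this package (author numbering, insertion codes, occupancies).
#'
#' @param model a `StructureModel`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  lines <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    name <- a$elety[i]
    # PDB atom-name column convention: element right-justified in cols 13-14
    name_f <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    lines[i] <- sprintf(
      "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i %% 100000, name_f, a$resid[i], substr(a$chain[i], 1, 1),
      a$resno[i], ifelse(a$ins[i] == "", " ", a$ins[i]),
      a$x[i], a$y[i], a$z[i], a$occ[i], 0, a$elesy[i])
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Construct a ResidueSequence
#'
#' @param letters 1-letter amino-acid string (20-letter alphabet plus X).
#' @param id identifier.
#' @param numbering author numbers parallel to `letters`; defaults to
#'   `1..nchar(letters)`.
#' @return object of class `ResidueSequence`.
#' @export
residue_sequence <- function(letters, id = "seq", numbering = NULL) {
  letters <- toupper(letters)
  n <- nchar(letters)
  if (is.null(numbering)) numbering <- seq_len(n)
  if (length(numbering) != n) {
    stop("numbering length ", length(numbering),
         " does not match sequence length ", n)
  }
  bad <- setdiff(unique(strsplit(letters, "")[[1]]), c(AA_ALPHABET, "X"))
  if (length(bad) > 0) stop("letters outside alphabet: ",
                            paste(bad, collapse = ""))
  structure(list(id = id, letters = letters, numbering = numbering),
            class = "ResidueSequence")
}

#' @export
print.ResidueSequence <- function(x, ...) {
  cat("ResidueSequence", x$id, ":", nchar(x$letters), "residues (",
      x$numbering[1], "-", x$numbering[length(x$numbering)], ")\n")
  invisible(x)
}

#' Extract the 1-letter sequence of a chain
#'
#' Residues are emitted in author-number order; non-standard residues
#' (including HETATM amino acids such as MSE) map to `X`.
#'
#' @param model a `StructureModel`.
#' @param chain_id chain identifier.
#' @return a [residue_sequence()] whose numbering is the chain's author
#'   numbering.
#' @export
extract_sequence <- function(model, chain_id) {
  res <- chain_residues(model, chain_id)
  letters <- unname(AA_321[res$resid])
  letters[is.na(letters)] <- "X"
  residue_sequence(paste(letters, collapse = ""),
                   id = paste0(model$source_id, "_", chain_id),
                   numbering = res$resno)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return list of [residue_sequence()] in file order, sequences uppercased,
#'   numbering `1..n`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("not parseable as FASTA: ", path))
  if (length(set) == 0) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  lapply(seq_along(set), function(i) {
    residue_sequence(toupper(as.character(set[[i]])), id = ids[i])
  })
}

#' Write ResidueSequences as FASTA
#' @param seqs list of `ResidueSequence` (or a single one).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "ResidueSequence")) seqs <- list(seqs)
  lines <- unlist(lapply(seqs, function(s) c(paste0(">", s$id), s$letters)))
  writeLines(lines, path)
  invisible(path)
}
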