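# shared fixture builders and independent oracles

atom_row <- function(chain, resno, resid, elety, elesy, x, y, z,
                     occ = 1, ins = "") {
  data.frame(chain = chain, resno = resno, ins = ins, resid = resid,
             elety = elety, elesy = elesy, x = x, y = y, z = z, occ = occ)
}

# minimal hand-written PDB text (fixed-width ATOM records)
pdb_line <- function(serial, name, resid, chain, resno, x, y, z,
                     occ = 1, alt = " ", record = "ATOM  ", elem = NULL) {
  if (is.null(elem)) elem <- substr(name, 1, 1)
  sprintf("%s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, paste0(" ", name), alt, resid, chain, resno,
          x, y, z, occ, 0, elem)
}

write_pdb_fixture <- function(lines, file = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), file)
  file
}

# independent affine-gap global aligner: plain recursion over all alignment
# paths (match/insert/delete with gap-state tracking); feasible for the
# short sequences it is used on
brute_force_align_score <- function(a, b, submat, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, submat[av[i], bv[j]] + rec(i + 1, j + 1, 0L))
    }
    if (i <= length(av)) {  # gap in b
      pen <- gap_extend + if (state == 1L) 0 else gap_open
      best <- max(best, -pen + rec(i + 1, j, 1L))
    }
    if (j <= length(bv)) {  # gap in a
      pen <- gap_extend + if (state == 2L) 0 else gap_open
      best <- max(best, -pen + rec(i, j + 1, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# toy 2-letter pair potential over A (self-attracting) and D (self-repelling)
toy_potential <- function() {
  m <- matrix(c(-1, 0, 0, 1), 2, 2, dimnames = list(c("A", "D"), c("A", "D")))
  pair_potential(m)
}
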