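#' @useDynLib ankthermo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# 3-letter -> 1-letter map for the 20 standard amino acids. Everything else
# (MSE, PTR, ...) maps to "X"; waters/ions never reach the sequence layer.
AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

AA_ALPHABET <- sort(unname(AA_321))

# Kyte-Doolittle hydropathy (range -4.5..4.5).
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Formal side-chain charges at pH 7; histidine partial by convention.
AA_CHARGE <- c(D = -1, E = -1, K = 1, R = 1, H = 0.1)

default_charge_table <- function() AA_CHARGE

seq_letters <- function(seq) strsplit(seq$letters, "", fixed = TRUE)[[1]]
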