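# Canonical amino-acid reference tables used across the package.

#' Standard amino acids
#'
#' The 20 standard amino acids as one-letter codes, in alphabetical order.
#' This ordering is the canonical row/column order for substitution matrices
#' and frequency vectors throughout the package.
#'
#' @format Character vector of length 20.
#' @export
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA_CODES
#' @format `AA_THREE_TO_ONE` is a named character vector mapping three-letter
#'   residue names (as found in PDB files) to one-letter codes.
#' @export
AA_THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y"
)

#' @rdname AA_CODES
#' @format `AA_ONE_TO_THREE` is the inverse mapping.
#' @export
AA_ONE_TO_THREE <- stats::setNames(names(AA_THREE_TO_ONE),
                                   unname(AA_THREE_TO_ONE))

# Side-chain heavy-atom names per amino acid (PDB nomenclature).  Glycine has
# no side-chain heavy atom; by convention its CA stands in for the side chain
# wherever side-chain atoms are required (contact rule, fixtures).
SIDE_CHAIN_ATOMS <- list(
  A = "CB",
  C = c("CB", "SG"),
  D = c("CB", "CG", "OD1", "OD2"),
  E = c("CB", "CG", "CD", "OE1", "OE2"),
  F = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  G = character(0),
  H = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  I = c("CB", "CG1", "CG2", "CD1"),
  K = c("CB", "CG", "CD", "CE", "NZ"),
  L = c("CB", "CG", "CD1", "CD2"),
  M = c("CB", "CG", "SD", "CE"),
  N = c("CB", "CG", "OD1", "ND2"),
  P = c("CB", "CG", "CD"),
  Q = c("CB", "CG", "CD", "OE1", "NE2"),
  R = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  S = c("CB", "OG"),
  T = c("CB", "OG1", "CG2"),
  V = c("CB", "CG1", "CG2"),
  W = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  Y = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH")
)

#' Side-chain heavy-atom counts
#'
#' Canonical number of non-hydrogen side-chain atoms per amino acid.  Glycine
#' is reported as 1 because its CA atom is used in lieu of a side chain in the
#' residue contact rule.
#'
#' @return Named integer vector over the 20 amino acids (one-letter codes).
#' @export
side_chain_heavy_counts <- function() {
  n <- vapply(SIDE_CHAIN_ATOMS, length, integer(1))
  n[["G"]] <- 1L  # CA stands in for the glycine side chain
  n[AA_CODES]
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
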