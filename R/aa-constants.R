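# Bundled constant tables. All values are published constants; sources are
# named next to each table so they can be audited and swapped via config.

#' Amino-acid one-letter codes (standard 20)
#' @keywords internal
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Three-letter to one-letter residue code map
#' @keywords internal
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  UNK = "X"
)

AA1TO3 <- setNames(names(AA3TO1), AA3TO1)

# Van der Waals radii (Angstrom), Bondi-style single-atom set used for
# solvent accessibility. Unknown elements fall back to carbon with a warning.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# Theoretical maximum accessible surface areas (Angstrom^2) per residue,
# Tien et al. (2013) "Maximum allowed solvent accessibilites of residues in
# proteins", theoretical column. Used to normalize SASA into RSA percent.
MAX_ASA_TIEN <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167,
  Q = 225, E = 223, G = 104, H = 224, I = 197,
  L = 201, K = 236, M = 224, F = 240, P = 159,
  S = 155, T = 172, W = 285, Y = 263, V = 174
)

# Background amino-acid frequencies of UniProtKB/Swiss-Prot (release
# statistics, percent of residues), normalized to sum to 1. Default
# background for composition enrichment.
SWISSPROT_FREQ <- local({
  f <- c(
    A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37,
    Q = 3.93, E = 6.75, G = 7.07, H = 2.27, I = 5.96,
    L = 9.66, K = 5.84, M = 2.42, F = 3.86, P = 4.70,
    S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87
  )
  f / sum(f)
})

# BLOSUM62 substitution scores (standard half-bit matrix) over the 20
# standard amino acids; rescaled to [0, 1] on demand for conservation
# scoring (Valdar-style sum-of-pairs).
BLOSUM62 <- local({
  v <- c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-2,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-2, 4
  )
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  matrix(v, 20, 20, byrow = TRUE, dimnames = list(aa, aa))
})

# BLOSUM62 rescaled linearly so min score -> 0 and max score -> 1; this is
# the pairwise similarity m(a, b) used by the sum-of-pairs conservation
# score. Pairs involving a gap or an unknown residue score 0.
BLOSUM62_01 <- (BLOSUM62 - min(BLOSUM62)) / (max(BLOSUM62) - min(BLOSUM62))

#' Pairwise amino-acid similarity in [0, 1]
#'
#' Looks up the rescaled BLOSUM62 similarity for two one-letter residue
#' vectors. Gaps (`-`) and unknown residues score 0 against everything.
#'
#' @param a,b character vectors of one-letter codes (recycled).
#' @return numeric vector of similarities in `[0, 1]`.
#' @keywords internal
aa_similarity <- function(a, b) {
  out <- numeric(length(a))
  ok <- a %in% AA1 & b %in% AA1
  if (any(ok)) out[ok] <- BLOSUM62_01[cbind(a[ok], b[ok])]
  out
}
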