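# Amino-acid constant tables shared across the package.

# The 20 canonical residues, alphabetical by one-letter code.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Residues accepted in operational records: canonical 20 plus X (unknown).
AA_ALLOWED <- c(AA20, "X")

# Average residue masses in Da (monomer minus water, ExPASy values).
AA_AVG_MASS <- c(
  A = 71.0788,  C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519,  H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167,  Q = 128.1307, R = 156.1875,
  S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760
)
MASS_WATER <- 18.01524

# Background residue frequencies (BLOSUM62 marginals), used for profile
# log-odds and for null-sequence generation.
AA_BACKGROUND <- c(
  A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047,
  G = 0.074, H = 0.026, I = 0.068, K = 0.058, L = 0.099,
  M = 0.025, N = 0.045, P = 0.039, Q = 0.034, R = 0.052,
  S = 0.057, T = 0.051, V = 0.073, W = 0.013, Y = 0.032
)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

# Physicochemical property sets (Livingstone & Barton style), the basis of
# the 12-rank (0-11) column conservation score.
AA_PROPERTIES <- list(
  hydrophobic = c("I", "L", "V", "C", "A", "G", "M", "F", "Y", "W", "H", "K", "T"),
  polar       = c("Y", "W", "H", "K", "R", "E", "Q", "D", "N", "S", "T", "C"),
  small       = c("V", "C", "A", "G", "D", "N", "S", "T", "P"),
  proline     = "P",
  tiny        = c("A", "G", "S"),
  aliphatic   = c("I", "L", "V"),
  aromatic    = c("F", "Y", "W", "H"),
  positive    = c("H", "K", "R"),
  negative    = c("D", "E"),
  charged     = c("H", "K", "R", "D", "E")
)

# Logical matrix: 20 residues x 10 properties.
aa_property_matrix <- function() {
  m <- vapply(AA_PROPERTIES, function(res) AA20 %in% res,
              logical(length(AA20)))
  rownames(m) <- AA20
  m
}

split_residues <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
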