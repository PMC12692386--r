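# Element data used throughout the molecular core. Hydrogens are implicit:
# every atom carries an implicit H count derived from its bond-order sum,
# charge and the standard valence table below.

.ELEMENTS <- c("B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "H")

# standard (monoisotopic-independent) average atomic masses, g/mol
.ATOMIC_MASS <- c(
  B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904,
  H = 1.008
)

# valence electrons (group electrons) per neutral atom
.VALENCE_ELECTRONS <- c(
  B = 3, C = 4, N = 5, O = 6, F = 7,
  P = 5, S = 6, Cl = 7, Br = 7, I = 7,
  H = 1
)

# allowed total valences (bond-order sum + implicit/explicit H) for the
# neutral element; lists are in increasing order so the smallest admissible
# valence >= bond sum decides the implicit H count
.DEFAULT_VALENCE <- list(
  B = 3, C = 4, N = 3, O = 2, F = 1,
  P = c(3, 5), S = c(2, 4, 6), Cl = 1, Br = 1, I = 1,
  H = 1
)

# allowed valences after a formal charge; only the small set of charge
# states common in drug-like chemistry is admitted, everything else is a
# valence error
.charged_valences <- function(element, charge) {
  if (charge == 0) return(.DEFAULT_VALENCE[[element]])
  key <- paste0(element, ifelse(charge > 0, "+", "-"), abs(charge))
  tab <- list(
    "C+1" = 3, "C-1" = 3,
    "N+1" = 4, "N-1" = 2,
    "O+1" = 3, "O-1" = 1,
    "S+1" = 3, "S-1" = 1,
    "P+1" = 4,
    "B-1" = 4
  )
  tab[[key]]
}

# elements that may carry the aromatic (lowercase) flag in SMILES
.AROMATIC_OK <- c("B", "C", "N", "O", "P", "S")

.is_known_element <- function(x) x %in% .ELEMENTS
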