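# Element data used by the molecular graph layer.

# Default valences per element; multi-valued entries list the accepted
# valence states in increasing order (used to assign implicit hydrogens
# to organic-subset atoms and to check valence on sanitization).
.ELEMENT_VALENCES <- list(
  H  = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L,
  Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L,
  As = c(3L, 5L), Se = c(2L, 4L, 6L), Br = 1L, I = 1L,
  Sn = 4L
)

# Elements that may be written without brackets in SMILES.
.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# Elements allowed to carry the aromatic flag.
.AROMATIC_ELEMENTS <- c("B", "C", "N", "O", "P", "S", "Se", "As")

# Two-letter element symbols recognized outside brackets.
.TWO_LETTER_ORGANIC <- c("Cl", "Br")

#' Allowed valences for an element at a given formal charge
#'
#' Returns the integer vector of valence states an element accepts, shifted
#' by formal charge following the usual octet bookkeeping (cationic N gains
#' a bond, anionic O loses one, carbanions/carbocations lose one, ...).
#' Unknown elements return `NA`, which disables valence checking for them.
#'
#' @param element Element symbol (e.g. `"N"`).
#' @param charge Integer formal charge.
#' @return Integer vector of allowed valences, or `NA` if unknown.
#' @keywords internal
allowed_valences <- function(element, charge = 0L) {
  base <- .ELEMENT_VALENCES[[element]]
  if (is.null(base)) return(NA_integer_)
  if (charge == 0L) return(base)
  if (element %in% c("N", "O", "P", "S", "Se", "As")) {
    v <- base + charge
  } else {
    # carbon, boron, halogens: any charge removes a bonding electron
    v <- base - abs(charge)
  }
  v <- v[v >= 0L]
  if (length(v) == 0L) 0L else v
}
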