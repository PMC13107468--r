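# Physical constants and element data.

#' @noRd
BOHR_PER_ANGSTROM <- 1.8897261254535

#' @noRd
KJMOL_PER_HARTREE <- 2625.499639

# Elements supported by the geometry layer (nuclear charge by symbol).
.element_z <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18
)

#' Nuclear charge for element symbols
#' @param elements character vector of element symbols.
#' @return integer vector of nuclear charges.
#' @noRd
elementZ <- function(elements) {
  z <- .element_z[elements]
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(elements[is.na(z)]), collapse = ", "))
  }
  unname(z)
}
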