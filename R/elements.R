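#' Monoisotopic element masses
#'
#' Masses (Da) of the most abundant isotope of each supported element,
#' CODATA/NIST-derived, stated to at least six decimal places. The table is
#' the single mass scale behind every m/z computed by the package.
#'
#' @return A named numeric vector, element symbol -> monoisotopic mass (Da).
#' @examples
#' element_masses()[["O"]]
#' @export
element_masses <- function() {
  c(
    C  = 12.0,
    H  = 1.0078250319,
    N  = 14.0030740052,
    O  = 15.9949146221,
    S  = 31.9720706900,
    P  = 30.9737615100,
    Cl = 34.9688527100,
    Na = 22.9897692800
  )
}

#' Physical constants for ion mass arithmetic
#'
#' Proton and electron masses used when converting neutral monoisotopic
#' masses to singly charged adduct m/z values.
#'
#' @format Named numeric constants (Da).
#' @name mass_constants
NULL

#' @rdname mass_constants
#' @export
PROTON_MASS <- 1.007276

#' @rdname mass_constants
#' @export
ELECTRON_MASS <- 0.000549

#' @rdname mass_constants
#' @export
SODIUM_MASS <- 22.989770
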