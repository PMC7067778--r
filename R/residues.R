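#' Default residue alphabet
#'
#' The 20 proteinogenic amino acid residues plus N-methyl-phenylalanine
#' (the nonproteinogenic residue of the cyclic pentapeptide family).
#' A residue is an amino acid minus water; its monoisotopic mass is computed
#' from its elemental composition through [monoisotopic_mass()], so residue
#' and formula arithmetic share one mass scale. Leucine and isoleucine are
#' distinct entries with identical mass and carry the isobaric class label
#' `"Xle"`; tandem MS cannot tell them apart.
#'
#' @return A tibble with columns `name`, `formula` (residue composition),
#'   `mass` (Da), `n_methylated` (logical), `iso_class` (mass-equivalence
#'   label; equals `name` except for Leu/Ile).
#' @examples
#' alpha <- default_alphabet()
#' alpha[alpha$name == "NMePhe", ]
#' @export
default_alphabet <- function() {
  def <- c(
    Gly = "C2H3NO",   Ala = "C3H5NO",    Ser = "C3H5NO2",  Pro = "C5H7NO",
    Val = "C5H9NO",   Thr = "C4H7NO2",   Cys = "C3H5NOS",  Leu = "C6H11NO",
    Ile = "C6H11NO",  Asn = "C4H6N2O2",  Asp = "C4H5NO3",  Gln = "C5H8N2O2",
    Lys = "C6H12N2O", Glu = "C5H7NO3",   Met = "C5H9NOS",  His = "C6H7N3O",
    Phe = "C9H9NO",   Arg = "C6H12N4O",  Tyr = "C9H9NO2",  Trp = "C11H10N2O",
    NMePhe = "C10H11NO"
  )
  tibble::tibble(
    name = names(def),
    formula = unname(def),
    mass = vapply(def, monoisotopic_mass, numeric(1), USE.NAMES = FALSE),
    n_methylated = names(def) == "NMePhe",
    iso_class = ifelse(names(def) %in% c("Leu", "Ile"), "Xle", names(def))
  )
}

#' Look up residues by name
#'
#' @param names Character vector of residue names.
#' @param alphabet Residue table, by default [default_alphabet()].
#' @return The matching rows of `alphabet`, in input order.
#' @export
residues <- function(names, alphabet = default_alphabet()) {
  idx <- match(names, alphabet$name)
  if (anyNA(idx)) {
    stop("unknown residue(s): ",
         paste(sQuote(names[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  alphabet[idx, , drop = FALSE]
}
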