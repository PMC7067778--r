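#' Parse a molecular formula
#'
#' Parses plain-text molecular formulas such as `"C17H18ClO6"` into a named
#' count vector. Symbols are one capital letter optionally followed by one
#' lowercase letter; each may carry an integer count (default 1). Repeated
#' symbols accumulate. Parentheses, isotopes and charge annotations are not
#' supported.
#'
#' @param text A single formula string.
#' @return An object of class `mol_formula`: a named integer vector of
#'   element counts in Hill order (C, H, then alphabetical).
#' @examples
#' parse_formula("C17H18ClO6")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  known <- names(element_masses())
  counts <- integer(0)
  rest <- text
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[1L])) {
      stop("formula parse error in ", sQuote(text), ": unexpected token at ",
           sQuote(rest), call. = FALSE)
    }
    sym <- m[2L]
    if (!(sym %in% known)) {
      stop("formula parse error in ", sQuote(text), ": unknown element ",
           sQuote(sym), call. = FALSE)
    }
    n <- if (nzchar(m[3L])) as.integer(m[3L]) else 1L
    if (n == 0L) {
      stop("formula parse error in ", sQuote(text), ": zero count for ",
           sQuote(sym), call. = FALSE)
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
    rest <- substr(rest, nchar(m[1L]) + 1L, nchar(rest))
  }
  new_mol_formula(counts)
}

new_mol_formula <- function(counts) {
  counts <- counts[counts > 0L]
  if (length(counts) == 0L) {
    return(structure(integer(0), names = character(0),
                     class = "mol_formula"))
  }
  ord <- order_hill(names(counts))
  out <- as.integer(counts)[ord]
  names(out) <- names(counts)[ord]
  structure(out, class = "mol_formula")
}

order_hill <- function(symbols) {
  # Hill order: C first, H second, remaining elements alphabetical
  rank <- match(symbols, c("C", "H"), nomatch = NA_integer_)
  order(is.na(rank), rank, symbols)
}

#' @export
format.mol_formula <- function(x, ...) {
  if (length(x) == 0L) return("")
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula> ", format(x), "  (", round(monoisotopic_mass(x), 6),
      " Da)\n", sep = "")
  invisible(x)
}

#' Combine two molecular formulas
#'
#' Element-wise sum of counts; mass is additive under this operation.
#'
#' @param f1,f2 `mol_formula` objects (or formula strings).
#' @return A `mol_formula`.
#' @export
formula_add <- function(f1, f2) {
  f1 <- as_mol_formula(f1); f2 <- as_mol_formula(f2)
  all_sym <- union(names(f1), names(f2))
  counts <- vapply(all_sym, function(s) {
    (if (s %in% names(f1)) f1[[s]] else 0L) +
      (if (s %in% names(f2)) f2[[s]] else 0L)
  }, integer(1))
  new_mol_formula(counts)
}

as_mol_formula <- function(f) {
  if (inherits(f, "mol_formula")) f else parse_formula(f)
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of the monoisotopic masses of all atoms. Additive over
#' [formula_add()]; the empty formula has mass 0.
#'
#' @param f A `mol_formula` or formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")  # 18.010565
#' @export
monoisotopic_mass <- function(f) {
  f <- as_mol_formula(f)
  if (length(f) == 0L) return(0)
  sum(element_masses()[names(f)] * unclass(f))
}

#' m/z of a singly charged adduct ion
#'
#' Protonated ions: neutral mass + proton mass. Sodiated ions: neutral mass
#' + sodium mass - electron mass. Only +1 charge is modeled.
#'
#' @param neutral Neutral molecular formula (`mol_formula` or string).
#' @param adduct `"[M+H]+"` or `"[M+Na]+"`.
#' @return Ion m/z in Da per unit charge.
#' @examples
#' ion_mz("C30H45N5O5", "[M+H]+")   # 556.3493 at 4 dp
#' ion_mz("C11H18O4", "[M+Na]+")    # 237.1097 at 4 dp
#' @export
ion_mz <- function(neutral, adduct = c("[M+H]+", "[M+Na]+")) {
  adduct <- match.arg(adduct)
  m <- monoisotopic_mass(neutral)
  switch(adduct,
         "[M+H]+"  = m + PROTON_MASS,
         "[M+Na]+" = m + SODIUM_MASS - ELECTRON_MASS)
}

#' Ring-plus-double-bond equivalents
#'
#' RDBE = C + 1 + N/2 - (H + Cl)/2 on the neutral formula; O, S and Na do
#' not contribute and Cl counts as H. May be half-integer for ion (even
#' electron) formulas.
#'
#' @param f Neutral molecular formula (`mol_formula` or string).
#' @return RDBE (numeric).
#' @examples
#' rdbe("C30H45N5O5")  # 11
#' rdbe("C6H6")        # 4 (benzene)
#' @export
rdbe <- function(f) {
  f <- as_mol_formula(f)
  cnt <- function(s) if (s %in% names(f)) f[[s]] else 0L
  cnt("C") + 1 + cnt("N") / 2 - (cnt("H") + cnt("Cl")) / 2
}

#' Signed ppm mass error
#'
#' `(theoretical - measured) / measured * 1e6`. The sign convention makes a
#' measured mass above theory print a negative error, matching accurate-mass
#' dereplication tables where over-measured ions carry negative ppm.
#'
#' @param measured,theoretical Positive m/z values (vectorized).
#' @return Signed error in parts per million.
#' @examples
#' ppm_error(353.0793, 353.0786)  # -1.98 at 2 dp
#' @export
ppm_error <- function(measured, theoretical) {
  if (any(measured <= 0) || any(theoretical <= 0)) {
    stop("ppm_error() requires positive m/z values", call. = FALSE)
  }
  (theoretical - measured) / measured * 1e6
}

#' Round half-up to a fixed number of decimals
#'
#' Printed tables round half away from zero, not to even; used when
#' comparing recomputed masses and ppm errors against printed values.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
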