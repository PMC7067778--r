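#' Construct a cyclic peptide
#'
#' A head-to-tail cyclic peptide: an ordered residue list read N-to-C with
#' an amide bond from the last residue back to the first. Rotations of the
#' list denote the same molecule. Cyclization removes the water of the
#' linear peptide, so the neutral monoisotopic mass is the plain sum of
#' residue masses.
#'
#' Accepts residue names or a `"cyclo(...)"` string with `-` separators,
#' e.g. `"cyclo(NMePhe-Ala-Ile-Leu-Pro)"`.
#'
#' @param residues Character vector of residue names, or a single
#'   `cyclo(...)` string.
#' @param alphabet Residue table, by default [default_alphabet()].
#' @return An object of class `cyclic_peptide`: a residue tibble with the
#'   ring order as row order.
#' @examples
#' cyclic_peptide("cyclo(NMePhe-Ala-Ile-Leu-Pro)")
#' @export
cyclic_peptide <- function(residues, alphabet = default_alphabet()) {
  if (length(residues) == 1L && grepl("^cyclo\\(", residues)) {
    inner <- sub("^cyclo\\((.*)\\)$", "\\1", residues)
    residues <- strsplit(inner, "-", fixed = TRUE)[[1]]
  }
  if (length(residues) < 2L) {
    stop("a cyclic peptide needs at least 2 residues", call. = FALSE)
  }
  structure(residues(residues, alphabet), class = c("cyclic_peptide", "tbl_df",
                                                    "tbl", "data.frame"))
}

#' @export
print.cyclic_peptide <- function(x, ...) {
  cat("cyclo(", paste(x$name, collapse = "-"), ")  [M+H]+ ",
      round(precursor_mz(x), 4), "\n", sep = "")
  invisible(x)
}

#' Precursor m/z of a cyclic peptide
#'
#' The singly protonated molecular ion: sum of residue masses plus one
#' proton. Invariant under rotation of the ring.
#'
#' @param p A `cyclic_peptide`.
#' @return m/z of \[M+H\]+.
#' @examples
#' precursor_mz(cyclic_peptide("cyclo(NMePhe-Ala-Ile-Leu-Pro)"))  # 556.3493
#' @export
precursor_mz <- function(p) {
  sum(p$mass) + PROTON_MASS
}

#' Neutral molecular formula of a cyclic peptide
#'
#' Element-wise sum of the residue compositions (no water: the ring is
#' closed).
#'
#' @param p A `cyclic_peptide`.
#' @return A `mol_formula`.
#' @examples
#' format(peptide_formula(cyclic_peptide("cyclo(NMePhe-Ala-Ile-Leu-Pro)")))
#' @export
peptide_formula <- function(p) {
  Reduce(formula_add, lapply(p$formula, parse_formula))
}

#' Enumerate ring openings
#'
#' Gas-phase ring opening cleaves one of the n amide bonds, producing a
#' linear acylium that fragments sequentially. Opening the bond preceding
#' residue i yields the rotation starting at residue i; every opening is
#' labelled by its flanking residues (cleaved bond written
#' `before -> first`).
#'
#' @param p A `cyclic_peptide`.
#' @return A list of length n; each element has `start` (1-based index of
#'   the first residue of the linearized sequence), `site` (label of the
#'   cleaved bond), `residues` (character vector, N-to-C) and `masses`
#'   (their residue masses).
#' @export
ring_openings <- function(p) {
  n <- nrow(p)
  lapply(seq_len(n), function(i) {
    idx <- ((i - 1L + seq_len(n) - 1L) %% n) + 1L
    before <- p$name[((i - 2L) %% n) + 1L]
    list(start = i,
         site = paste0(before, "->", p$name[i]),
         residues = p$name[idx],
         masses = p$mass[idx])
  })
}

#' b-ion series of a linearized (ring-opened) peptide
#'
#' For an acylium produced by ring opening, the k-th b-ion is the sum of the
#' first k residue masses plus one proton; no water is added, so the
#' full-length ion b_n coincides with the precursor \[M+H\]+ of the parent
#' ring. The series is strictly increasing.
#'
#' @param residue_names Character vector of residue names, N-to-C.
#' @param alphabet Residue table.
#' @return Numeric vector of m/z values, `b1` to `bn`.
#' @examples
#' b_series(c("NMePhe", "Ala", "Ile", "Leu", "Pro"))
#' @export
b_series <- function(residue_names, alphabet = default_alphabet()) {
  stopifnot(length(residue_names) >= 1L)
  r <- residues(residue_names, alphabet)
  stats::setNames(cumsum(r$mass) + PROTON_MASS,
                  paste0("b", seq_along(residue_names)))
}

#' Theoretical cyclospectrum
#'
#' Union (with multiplicity) of the b-ion series over all n ring openings:
#' n(n-1) proper-prefix ions plus the n-fold shared full-length ion reported
#' once, i.e. n(n-1)+1 values before any mass-collision deduplication.
#'
#' @param p A `cyclic_peptide`.
#' @param dedup If `TRUE`, collapse masses equal within `1e-9` Da to a
#'   deduplicated view.
#' @return Sorted numeric vector of theoretical b-ion m/z values.
#' @examples
#' length(cyclospectrum(cyclic_peptide("cyclo(NMePhe-Ala-Ile-Leu-Pro)")))  # 21
#' @export
cyclospectrum <- function(p, dedup = FALSE) {
  openings <- ring_openings(p)
  n <- nrow(p)
  proper <- unlist(lapply(openings, function(o) {
    cumsum(o$masses)[seq_len(n - 1L)] + PROTON_MASS
  }), use.names = FALSE)
  out <- sort(c(proper, precursor_mz(p)))
  if (dedup) out <- out[c(TRUE, diff(out) > 1e-9)]
  out
}

#' Canonical rotation key of a residue sequence
#'
#' The lexicographically smallest rotation of the residue-name vector;
#' rotations of a ring share one key. With `collapse_xle = TRUE` Leu/Ile
#' are first mapped to their shared isobaric class label `Xle`. With
#' `merge_reflections = TRUE` the key is the smaller of the two reading
#' directions' keys, so a ring and its reversal share one key: the
#' multiset of b-ions over all ring openings is identical for the two
#' orientations, making the direction undeterminable from single-stage
#' fragment masses.
#'
#' @param residue_names Character vector of residue names.
#' @param collapse_xle Collapse Leu/Ile to `Xle` before keying.
#' @param merge_reflections Merge the two reading directions.
#' @return A single string, residues joined by `-`.
#' @examples
#' rotation_key(c("Ile", "Leu", "Pro", "NMePhe", "Ala"))
#' @export
rotation_key <- function(residue_names, collapse_xle = FALSE,
                         merge_reflections = FALSE) {
  if (collapse_xle) {
    residue_names[residue_names %in% c("Leu", "Ile")] <- "Xle"
  }
  min_rot <- function(nm) {
    n <- length(nm)
    min(vapply(seq_len(n), function(i) {
      paste(nm[((i - 1L + seq_len(n) - 1L) %% n) + 1L], collapse = "-")
    }, character(1)))
  }
  key <- min_rot(residue_names)
  if (merge_reflections) key <- min(key, min_rot(rev(residue_names)))
  key
}
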