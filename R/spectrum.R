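#' Construct an MS/MS spectrum
#'
#' @param precursor_mz Precursor ion m/z (> 0).
#' @param mz Fragment m/z values (> 0).
#' @param intensity Non-negative intensities; defaults to 1 for peak lists
#'   that carry none.
#' @return An object of class `msms_spectrum`: a list with `precursor_mz`
#'   and a `peaks` tibble sorted by m/z.
#' @export
msms_spectrum <- function(precursor_mz, mz, intensity = rep(1, length(mz))) {
  stopifnot(precursor_mz > 0, length(mz) == length(intensity),
            all(mz > 0), all(intensity >= 0))
  ord <- order(mz)
  structure(list(precursor_mz = precursor_mz,
                 peaks = tibble::tibble(mz = mz[ord],
                                        intensity = intensity[ord])),
            class = "msms_spectrum")
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat("<msms_spectrum> precursor ", round(x$precursor_mz, 4), ", ",
      nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

#' Read an MGF peak list
#'
#' Minimal reader for centroided MGF files: one or more
#' `BEGIN IONS`/`END IONS` blocks with `PEPMASS=` (first field used) and
#' whitespace-separated `m/z intensity` peak lines. Written by hand because
#' no installed package parses MGF.
#'
#' @param path File path.
#' @return A list of `msms_spectrum` objects (one per block).
#' @export
read_mgf <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path,
         call. = FALSE)
  }
  lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    pep <- grep("^PEPMASS=", block, value = TRUE)
    if (length(pep) == 0L) stop("MGF block without PEPMASS in ", path,
                                call. = FALSE)
    prec <- as.numeric(strsplit(sub("^PEPMASS=", "", pep[1L]), "[ \t]+")[[1]][1])
    peak_lines <- block[grepl("^[0-9]", block)]
    if (length(peak_lines) == 0L) return(msms_spectrum(prec, numeric(0),
                                                       numeric(0)))
    mat <- do.call(rbind, lapply(strsplit(peak_lines, "[ \t]+"), function(f) {
      as.numeric(f[1:2])
    }))
    inten <- ifelse(is.na(mat[, 2]), 1, mat[, 2])
    msms_spectrum(prec, mat[, 1], inten)
  })
}

#' Write an MGF peak list
#'
#' @param spectra A single `msms_spectrum` or a list of them.
#' @param path Output path.
#' @param titles Optional character vector of TITLE fields.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path, titles = NULL) {
  if (inherits(spectra, "msms_spectrum")) spectra <- list(spectra)
  out <- unlist(lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    c("BEGIN IONS",
      if (!is.null(titles)) paste0("TITLE=", titles[i]),
      paste0("PEPMASS=", format(s$precursor_mz, digits = 10)),
      "CHARGE=1+",
      sprintf("%.5f %.3f", s$peaks$mz, s$peaks$intensity),
      "END IONS", "")
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read a plain two-column peak list
#'
#' Whitespace- or comma-separated `m/z intensity` lines; lines starting with
#' `#` are ignored. A single-column file is read as m/z with unit
#' intensities.
#'
#' @param path File path.
#' @param precursor_mz Precursor m/z (two-column text carries none).
#' @return An `msms_spectrum`.
#' @export
read_peaks <- function(path, precursor_mz) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[,; \t]+")
  mz <- vapply(fields, function(f) as.numeric(f[1]), numeric(1))
  inten <- vapply(fields, function(f) {
    if (length(f) >= 2) as.numeric(f[2]) else 1
  }, numeric(1))
  msms_spectrum(precursor_mz, mz, inten)
}

#' Annotate an MS/MS spectrum with ring-opening b-ion ladders
#'
#' Matches every theoretical b-ion of every ring opening to the nearest
#' observed peak; an ion is matched when the nearest peak lies within
#' `tol`. One observed peak may satisfy several theoretical ions. The
#' full-length ion b_n is shared by all openings and carries the same
#' annotation in each. Per-opening coverage counts matched proper-prefix
#' ions over n-1; openings are ranked by coverage.
#'
#' @param p A `cyclic_peptide`.
#' @param spectrum An `msms_spectrum`.
#' @param tol Absolute matching tolerance in Da (> 0); default 0.02.
#' @return A list with `annotations` (tibble: `site`, `ion`, `theoretical`,
#'   `observed`, `delta`, `matched`, `lost_residue` — the residue whose loss
#'   from the precursor produces the ion, `NA` for b_n) and `coverage`
#'   (tibble: `site`, `coverage`, sorted decreasing).
#' @examples
#' pep <- cyclic_peptide("cyclo(NMePhe-Ala-Ile-Leu-Pro)")
#' s <- msms_spectrum(556.35, c(459.30, 346.21, 233.13, 162.09))
#' annotate_spectrum(pep, s, tol = 0.05)$coverage
#' @export
annotate_spectrum <- function(p, spectrum, tol = 0.02) {
  stopifnot(tol > 0)
  n <- nrow(p)
  openings <- ring_openings(p)
  obs <- spectrum$peaks$mz
  ann <- do.call(rbind, lapply(openings, function(o) {
    theo <- stats::setNames(cumsum(o$masses) + PROTON_MASS,
                            paste0("b", seq_len(n)))
    # sequential-loss labels: b_k arises from b_{k+1} by loss of residue
    # k+1, so printed ladders tag b_{n-1} with the residue next to the
    # opened bond ("-Pro" for the Pro->NMePhe opening); b_n loses nothing
    lost <- c(o$residues[-1L], NA)
    data.frame(site = o$site, ion = names(theo), theoretical = unname(theo),
               lost_residue = lost, stringsAsFactors = FALSE)
  }))
  if (length(obs) == 0L) {
    ann$observed <- NA_real_
    ann$delta <- NA_real_
    ann$matched <- FALSE
  } else {
    nearest <- vapply(ann$theoretical, function(t) obs[which.min(abs(obs - t))],
                      numeric(1))
    delta <- nearest - ann$theoretical
    ann$observed <- ifelse(abs(delta) <= tol, nearest, NA_real_)
    ann$delta <- ifelse(abs(delta) <= tol, delta, NA_real_)
    ann$matched <- abs(delta) <= tol
  }
  ann <- tibble::as_tibble(ann[, c("site", "ion", "theoretical", "observed",
                                   "delta", "matched", "lost_residue")])
  cov <- vapply(openings, function(o) {
    rows <- ann$site == o$site & ann$ion != paste0("b", n)
    sum(ann$matched[rows]) / (n - 1L)
  }, numeric(1))
  coverage <- tibble::tibble(site = vapply(openings, `[[`, character(1), "site"),
                             coverage = cov)
  coverage <- coverage[order(-coverage$coverage, coverage$site), ]
  list(annotations = ann, coverage = coverage)
}
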