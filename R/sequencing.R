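#' De novo sequencing of a cyclic peptide from its MS/MS spectrum
#'
#' Leaderboard growth of linear prefixes: starting from single residues,
#' prefixes are extended one residue at a time over the alphabet; after each
#' round only the `beam` best prefixes survive (scored by the number of
#' prefix b-ions matching an observed peak within `tol`; ties broken
#' deterministically toward lighter prefixes), and prefixes heavier than
#' the precursor are pruned. A wide enough beam makes the search exhaustive. A prefix of length `ring_size` closes the
#' ring only when its residue sum plus a proton lies within `tol` of the
#' precursor. Closed rings are scored by the number of observed peaks
#' explained by their deduplicated cyclospectrum, deduplicated by rotation
#' class, and ranked by score, then |precursor delta|, then canonical key.
#'
#' Because Leu and Ile are isobaric the search runs over one representative
#' per residue mass and reports the collapsed `Xle` class by default;
#' `expand_xle = TRUE` re-expands every Xle position into both assignments.
#' A ring and its reversal produce identical cyclospectra (every contiguous
#' cyclic substring of one is a reversed substring of the other), so the
#' reading direction cannot be determined from b-ion masses; by default the
#' two orientations are reported as one candidate under the
#' reflection-merged canonical key (`merge_reflections = FALSE` keeps them
#' separate, in which case both orientations appear with equal score).
#'
#' @param precursor Precursor \[M+H\]+ m/z.
#' @param spectrum An `msms_spectrum` (its peak m/z values are used).
#' @param alphabet Residue table, by default [default_alphabet()].
#' @param ring_size Number of residues in the ring (>= 2).
#' @param tol Absolute mass tolerance in Da (> 0).
#' @param keep Maximum number of candidates returned (>= 1).
#' @param beam Leaderboard width (number of prefixes retained per round).
#' @param expand_xle Report explicit Leu/Ile assignments instead of the
#'   collapsed class.
#' @param merge_reflections Report the two (indistinguishable) reading
#'   directions as one candidate.
#' @return A tibble of candidates: `sequence` (canonical rotation key),
#'   `matched_peaks` (observed peaks explained), `coverage` (matched
#'   theoretical ions / distinct theoretical ions), `precursor_delta`.
#'   Zero rows when no prefix closes the ring.
#' @examples
#' pep <- cyclic_peptide("cyclo(Gly-Gly)")
#' s <- msms_spectrum(115.0502, 58.0287)
#' sequence_candidates(115.0502, s, ring_size = 2, tol = 0.01)
#' @export
sequence_candidates <- function(precursor, spectrum,
                                alphabet = default_alphabet(),
                                ring_size = 5, tol = 0.02, keep = 10,
                                beam = 1000, expand_xle = FALSE,
                                merge_reflections = TRUE) {
  stopifnot(ring_size >= 2, keep >= 1, tol > 0)
  if (nrow(alphabet) == 0L) stop("empty residue alphabet", call. = FALSE)
  obs <- sort(spectrum$peaks$mz)
  # one representative residue per isobaric class, named by the class label
  rep_idx <- !duplicated(alphabet$iso_class)
  res_names <- alphabet$iso_class[rep_idx]
  res_mass <- alphabet$mass[rep_idx]

  matches_peak <- function(mz) {
    if (length(obs) == 0L) return(rep(FALSE, length(mz)))
    i <- findInterval(mz, obs)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, length(obs))
    pmin(abs(mz - obs[lo]), abs(mz - obs[hi])) <= tol
  }

  # leaderboard state: matrix of residue indices + cumulative mass + score
  seqs <- matrix(seq_along(res_mass), ncol = 1)
  mass <- res_mass
  score <- as.integer(matches_peak(mass + PROTON_MASS))
  ok <- mass + PROTON_MASS <= precursor + tol
  seqs <- seqs[ok, , drop = FALSE]; mass <- mass[ok]; score <- score[ok]

  for (len in seq_len(ring_size - 1L)) {
    if (nrow(seqs) == 0L) break
    # trim to beam before extending; deterministic order (score descending,
    # then lighter prefix first, then insertion order via stable sort)
    if (nrow(seqs) > beam) {
      sel <- order(-score, mass)[seq_len(beam)]
      seqs <- seqs[sel, , drop = FALSE]; mass <- mass[sel]; score <- score[sel]
    }
    k <- length(res_mass)
    nseq <- nrow(seqs)
    seqs <- cbind(seqs[rep(seq_len(nseq), each = k), , drop = FALSE],
                  rep(seq_len(k), times = nseq))
    mass <- rep(mass, each = k) + rep(res_mass, times = nseq)
    score <- rep(score, each = k) +
      as.integer(matches_peak(mass + PROTON_MASS))
    ok <- mass + PROTON_MASS <= precursor + tol
    seqs <- seqs[ok, , drop = FALSE]; mass <- mass[ok]; score <- score[ok]
  }
  if (nrow(seqs) == 0L) return(empty_candidates())
  closes <- abs(mass + PROTON_MASS - precursor) <= tol
  seqs <- seqs[closes, , drop = FALSE]
  mass <- mass[closes]
  if (nrow(seqs) == 0L) return(empty_candidates())

  cand <- lapply(seq_len(nrow(seqs)), function(i) {
    nm <- res_names[seqs[i, ]]
    key <- rotation_key(nm, merge_reflections = merge_reflections)
    list(names = nm, key = key, mass = mass[i])
  })
  keys <- vapply(cand, `[[`, character(1), "key")
  cand <- cand[!duplicated(keys)]

  rep_alpha <- tibble::tibble(name = res_names, formula = NA_character_,
                              mass = res_mass, n_methylated = FALSE,
                              iso_class = res_names)
  scored <- lapply(cand, function(cn) {
    ring <- structure(rep_alpha[match(cn$names, rep_alpha$name), ],
                      class = c("cyclic_peptide", "tbl_df", "tbl",
                                "data.frame"))
    theo <- cyclospectrum(ring, dedup = TRUE)
    matched_theo <- sum(matches_peak(theo))
    explained <- if (length(obs)) {
      sum(vapply(obs, function(o) any(abs(theo - o) <= tol), logical(1)))
    } else 0L
    tibble::tibble(sequence = cn$key,
                   matched_peaks = explained,
                   coverage = matched_theo / length(theo),
                   precursor_delta = cn$mass + PROTON_MASS - precursor)
  })
  out <- do.call(rbind, scored)
  out <- out[order(-out$matched_peaks, round(abs(out$precursor_delta), 9),
                   out$sequence), , drop = FALSE]
  out <- utils::head(out, keep)
  if (expand_xle) out <- expand_xle_candidates(out)
  out
}

empty_candidates <- function() {
  tibble::tibble(sequence = character(0), matched_peaks = integer(0),
                 coverage = numeric(0), precursor_delta = numeric(0))
}

expand_xle_candidates <- function(cands) {
  rows <- lapply(seq_len(nrow(cands)), function(i) {
    nm <- strsplit(cands$sequence[i], "-", fixed = TRUE)[[1]]
    pos <- which(nm == "Xle")
    if (length(pos) == 0L) return(cands[i, ])
    grids <- expand.grid(rep(list(c("Leu", "Ile")), length(pos)),
                         stringsAsFactors = FALSE)
    do.call(rbind, lapply(seq_len(nrow(grids)), function(g) {
      nm2 <- nm
      nm2[pos] <- unlist(grids[g, ])
      out <- cands[i, ]
      out$sequence <- rotation_key(nm2)
      out
    }))
  })
  out <- do.call(rbind, rows)
  out[!duplicated(out$sequence), , drop = FALSE]
}
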