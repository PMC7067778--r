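# Exhaustive enumeration oracle for cyclic-peptide sequencing: every
# ring_size-tuple over the alphabet whose residue sum closes the precursor
# within tol, reported as deduplicated canonical rotation keys. Independent
# of the leaderboard search path.
enumerate_rings <- function(precursor, alphabet, ring_size, tol,
                            merge_reflections = TRUE) {
  rep_idx <- !duplicated(alphabet$iso_class)
  nm <- alphabet$iso_class[rep_idx]
  ms <- alphabet$mass[rep_idx]
  grid <- as.matrix(expand.grid(rep(list(seq_along(ms)), ring_size)))
  total <- rowSums(matrix(ms[grid], nrow(grid)))
  hit <- abs(total + cyclometab::PROTON_MASS - precursor) <= tol
  keys <- apply(grid[hit, , drop = FALSE], 1L, function(idx) {
    rotation_key(nm[idx], merge_reflections = merge_reflections)
  })
  sort(unique(keys))
}

# small five-residue alphabet for exhaustive tests
mini_alphabet <- function() {
  a <- default_alphabet()
  a[a$name %in% c("Gly", "Ala", "Pro", "Val", "Phe"), ]
}

# tiny in-code feature table: 4 features x 4 samples with controllable
# areas, isotope flags and retention times
tiny_table <- function(areas = NULL,
                       isotope = c(FALSE, FALSE, FALSE, FALSE),
                       rt = c(5, 10, 20, 26),
                       matrix_level = "filtrate") {
  features <- tibble::tibble(
    feature_id = paste0("F", 1:4),
    mz = c(200.1, 350.2, 500.3, 650.4),
    rt_min = rt,
    isotope_flag = isotope)
  samples <- tibble::tibble(
    sample_id = paste0("S", 1:4),
    strain = c("HB-01", "HB-02", "WL-01", "WL-02"),
    host = c("highbush", "highbush", "wild", "wild"),
    medium = c("ML", "PDB", "ML", "PDB"),
    matrix = matrix_level)
  if (is.null(areas)) {
    areas <- matrix(2e4, 4, 4)
  }
  dimnames(areas) <- list(features$feature_id, samples$sample_id)
  feature_table(features, areas, samples)
}

# Gaussian two-class simulation for the OPLS property tests: n samples,
# p features, n_inf informative columns separated by `effect` within-class
# standard deviations
sim_gauss <- function(n = 30, p = 200, n_inf = 30, effect = 3, seed = 1) {
  stopifnot(n %% 2 == 0)
  set.seed(seed)
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  if (n_inf > 0) {
    shift <- ifelse(y == "a", effect / 2, -effect / 2)
    X[, seq_len(n_inf)] <- X[, seq_len(n_inf)] + shift
  }
  list(X = X, y = y)
}

ellisiiamide_a <- function() cyclic_peptide("cyclo(NMePhe-Ala-Ile-Leu-Pro)")
ellisiiamide_b <- function() cyclic_peptide("cyclo(NMePhe-Val-Val-Leu-Pro)")
ellisiiamide_c <- function() cyclic_peptide("cyclo(NMePhe-Ile-Ile-Leu-Pro)")
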