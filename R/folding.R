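#' Partition function and base-pair probabilities
#'
#' McCaskill-style O(n^3) inside/outside recursions consistent with
#' [evaluate_energy()]: every pseudoknot-free structure with hairpin loops of
#' at least 3 nt (and interior loops within the model's `maxloop` cap) is
#' counted exactly once with Boltzmann weight exp(-dG/RT).
#'
#' @param sequence RNA string.
#' @param model an [energy_model()].
#' @param pseudo optional [pseudo_energy_model()] (reactivity restraints).
#' @param profile reactivity profile used with `pseudo`.
#' @param pair_probs compute the base-pair probability matrix (outside
#'   algorithm); disable for speed when only log Z is needed.
#' @return list with `logZ`, `pair_prob` (n x n matrix, upper triangle),
#'   and `paired_prob` (per-nucleotide sum over partners).
#' @export
partition_function <- function(sequence, model = energy_model(),
                               pseudo = NULL, profile = NULL,
                               pair_probs = TRUE) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  g <- pseudo_energy_vector(pseudo, profile, n, model)
  res <- cpp_partition(seq_codes(sequence), unclass(model), g, pair_probs)
  pp <- res$pair_prob
  res$paired_prob <- rowSums(pp) + colSums(pp)
  res
}

#' Minimum free energy structure
#'
#' Returns a structure minimizing [evaluate_energy()] over the same search
#' space as [partition_function()].  Among degenerate optima the traceback is
#' deterministic: alternatives are examined in a fixed order with unpaired
#' states preferred, so repeated calls return the same structure.
#'
#' @inheritParams partition_function
#' @return a `secondary_structure` with attribute `energy`.
#' @export
mfe_fold <- function(sequence, model = energy_model(), pseudo = NULL,
                     profile = NULL) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  g <- pseudo_energy_vector(pseudo, profile, n, model)
  res <- cpp_mfe(seq_codes(sequence), unclass(model), g)
  out <- secondary_structure(sequence, res$pairs)
  attr(out, "energy") <- res$energy
  out
}

#' Stochastic sampling from the Boltzmann ensemble
#'
#' Draws `n` independent structures by stochastic traceback through the
#' partition-function arrays, so each structure appears with probability
#' proportional to exp(-dG/RT).  Deterministic for a fixed seed.
#'
#' @inheritParams partition_function
#' @param n number of samples (the study design uses 1000).
#' @param seed integer seed for the sampler's RNG stream.
#' @return a `structure_ensemble`: list with `sequence`, `pairs` (n x length
#'   integer matrix of partner tables), `n`, and `seed`.
#' @export
sample_structures <- function(sequence, model = energy_model(), pseudo = NULL,
                              profile = NULL, n = 1000, seed = 1L) {
  sequence <- normalize_rna(sequence)
  len <- nchar(sequence)
  g <- pseudo_energy_vector(pseudo, profile, len, model)
  pairs <- withr::with_seed(seed,
    cpp_sample(seq_codes(sequence), unclass(model), g, as.integer(n)))
  structure(list(sequence = sequence, pairs = pairs, n = as.integer(n),
                 seed = as.integer(seed)),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat("structure_ensemble:", x$n, "samples of", nchar(x$sequence),
      "nt (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Extract one ensemble member as a structure
#' @param ensemble a `structure_ensemble`.
#' @param i member index.
#' @export
ensemble_member <- function(ensemble, i) {
  secondary_structure(ensemble$sequence, ensemble$pairs[i, ],
                      validate = FALSE)
}

#' Exhaustive structure enumeration (testing oracle)
#'
#' Enumerates every pseudoknot-free structure with hairpin loops >= 3 nt over
#' canonical (Watson-Crick + GU) pairs, scoring each with
#' [evaluate_energy()].  Guarded to sequences of at most 20 nt.
#'
#' @inheritParams partition_function
#' @param max_len combinatorial guard (default 20).
#' @return list with `structures` (list of `secondary_structure`) and
#'   `energies` (numeric vector).
#' @export
enumerate_structures <- function(sequence, model = energy_model(),
                                 pseudo = NULL, profile = NULL,
                                 max_len = 20L) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  if (n > max_len)
    stop("enumeration refused for sequences longer than ", max_len, " nt")
  codes <- seq_codes(sequence)
  can_pair <- function(i, j) {
    a <- codes[i]; b <- codes[j]
    (a == 0 && b == 3) || (a == 3 && b == 0) || (a == 1 && b == 2) ||
      (a == 2 && b == 1) || (a == 2 && b == 3) || (a == 3 && b == 2)
  }
  # all pair sets on [i..j]; memoized on interval
  memo <- new.env(parent = emptyenv())
  enum <- function(i, j) {
    if (i >= j) return(list(list()))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- enum(i + 1, j)            # i unpaired
    for (k in if (j >= i + 4) (i + 4):j else integer(0)) {
      if (!can_pair(i, k)) next
      left <- enum(i + 1, k - 1)
      right <- enum(k + 1, j)
      for (L in left) for (R in right)
        out[[length(out) + 1]] <- c(list(c(i, k)), L, R)
    }
    memo[[key]] <- out
    out
  }
  sets <- if (n >= 2) enum(1, n) else list(list())
  structures <- lapply(sets, function(ps) {
    pairs <- integer(n)
    for (pr in ps) { pairs[pr[1]] <- pr[2]; pairs[pr[2]] <- pr[1] }
    secondary_structure(sequence, pairs, validate = FALSE)
  })
  energies <- vapply(structures, evaluate_energy, numeric(1),
                     model = model, pseudo = pseudo, profile = profile)
  list(structures = structures, energies = energies)
}
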