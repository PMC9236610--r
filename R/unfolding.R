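#' Junction regions and spliceosome footprints
#'
#' A junction region is declared by the number of exonic nucleotides
#' upstream of the exon-intron boundary and intronic nucleotides downstream,
#' and resolves to the 1-based interval
#' `[junction_offset - exonic + 1, junction_offset + intronic]`.
#' The donor splice site itself spans the last 3 exonic and first 6 intronic
#' nucleotides (the 9-mer paired by U1 snRNA).
#'
#' @param exonic_extent,intronic_extent nonnegative counts.
#' @return a `junction_region`.
#' @export
junction_region <- function(exonic_extent, intronic_extent) {
  stopifnot(exonic_extent >= 0, intronic_extent >= 0)
  structure(list(exonic = as.integer(exonic_extent),
                 intronic = as.integer(intronic_extent)),
            class = "junction_region")
}

#' @rdname junction_region
#' @param region a `junction_region`.
#' @param js a junction sequence (see [gen_junction_sequence()]) or a
#'   junction offset integer.
#' @return `resolve_region`: integer vector `c(start, end)`.
#' @export
resolve_region <- function(region, js) {
  off <- if (is.list(js)) js$junction_offset else as.integer(js)
  n <- if (is.list(js)) nchar(js$sequence) else NA_integer_
  start <- off - region$exonic + 1L
  end <- off + region$intronic
  if (start < 1 || (!is.na(n) && end > n))
    stop("region [", start, ", ", end, "] exceeds sequence bounds")
  c(start = start, end = end)
}

#' Spliceosome footprint table
#'
#' Minimum pre-mRNA extents around the 5' splice site enclosed by the
#' spliceosome at four assembly stages, as counted from cryo-EM structures:
#' Pre-B (2 exonic, 8 intronic), B (10, 17), Pre-Bact (9, 20),
#' Bact (12, 31).
#'
#' @return data.frame with columns `stage`, `exonic`, `intronic`.
#' @export
footprint_table <- function() {
  data.frame(stage = c("PreB", "B", "PreBact", "Bact"),
             exonic = c(2L, 10L, 9L, 12L),
             intronic = c(8L, 17L, 20L, 31L),
             stringsAsFactors = FALSE)
}

#' @rdname footprint_table
#' @param stage one of "PreB", "B", "PreBact", "Bact", or "splice_site"
#'   (3 exonic + 6 intronic).
#' @param js junction sequence or offset; when given, the region is resolved
#'   and returned with attribute `interval`.
#' @export
footprint_region <- function(stage, js = NULL) {
  if (stage == "splice_site") {
    reg <- junction_region(3, 6)
  } else {
    tab <- footprint_table()
    row <- tab[tab$stage == stage, ]
    if (nrow(row) != 1) stop("unknown footprint stage '", stage, "'")
    reg <- junction_region(row$exonic, row$intronic)
  }
  if (!is.null(js)) attr(reg, "interval") <- resolve_region(reg, js)
  reg
}

#' Force a region single-stranded
#'
#' Removes every base pair with at least one endpoint inside the region
#' (CT semantics: the partner column is set to 0), leaving all other pairs
#' untouched.
#'
#' @param x a `secondary_structure`.
#' @param interval integer `c(start, end)` (or a `junction_region` plus
#'   `js` to resolve it).
#' @param js junction sequence/offset when `interval` is a `junction_region`.
#' @return a `secondary_structure`.
#' @export
unfold_region <- function(x, interval, js = NULL) {
  if (inherits(interval, "junction_region"))
    interval <- resolve_region(interval, js)
  p <- x$pairs
  n <- length(p)
  inside <- seq_len(n) >= interval[1] & seq_len(n) <= interval[2]
  hit <- which(inside & p > 0)
  partners <- p[hit]
  p[hit] <- 0L
  p[partners] <- 0L
  secondary_structure(x$sequence, p, validate = FALSE)
}

#' Unfolding free energy of a region
#'
#' The nonequilibrium cost of disrupting a region of a fixed structure
#' without letting the RNA refold:
#' \deqn{\Delta G^\ddagger = \Delta G(\mathrm{unfolded}) -
#'       \Delta G(\mathrm{folded}) \ge 0}
#' computed with [evaluate_energy()] on the structure before and after
#' [unfold_region()].  Zero when the region is already single-stranded.
#' Pseudo-energies, when supplied, enter both evaluations and cancel for
#' positions unpaired in both.
#'
#' @inheritParams unfold_region
#' @param model an [energy_model()].
#' @param pseudo optional [pseudo_energy_model()].
#' @param profile reactivity profile used with `pseudo`.
#' @return free energy in kcal/mol.
#' @export
delta_g_unfold <- function(x, interval, model = energy_model(),
                           pseudo = NULL, profile = NULL, js = NULL) {
  if (inherits(interval, "junction_region"))
    interval <- resolve_region(interval, js)
  unfolded <- unfold_region(x, interval)
  evaluate_energy(unfolded, model, pseudo, profile) -
    evaluate_energy(x, model, pseudo, profile)
}

#' Ensemble unfolding statistics
#'
#' Computes the unfolding free energy of a region for every member of a
#' Boltzmann ensemble and summarizes the distribution by its population
#' mean, SD, skewness, and excess kurtosis (skew and kurtosis defined as 0
#' for zero-variance ensembles).  `mfe_delta_g` is the unfolding energy of
#' the single MFE structure under the same inputs.
#'
#' @param ensemble a `structure_ensemble` from [sample_structures()].
#' @param interval region interval or `junction_region` (+ `js`).
#' @inheritParams delta_g_unfold
#' @return list with `mean`, `sd`, `skew`, `kurtosis`, `mfe_delta_g`,
#'   `n`, and the per-member `values`.
#' @export
ensemble_unfolding_stats <- function(ensemble, interval,
                                     model = energy_model(), pseudo = NULL,
                                     profile = NULL, js = NULL) {
  stopifnot(inherits(ensemble, "structure_ensemble"), ensemble$n >= 1)
  if (inherits(interval, "junction_region"))
    interval <- resolve_region(interval, js)
  codes <- seq_codes(ensemble$sequence)
  len <- length(codes)
  g <- pseudo_energy_vector(pseudo, profile, len, model)
  folded <- cpp_energy_batch(codes, ensemble$pairs, unclass(model), g)
  open_pairs <- ensemble$pairs
  inside <- seq_len(len) >= interval[1] & seq_len(len) <= interval[2]
  for (r in seq_len(nrow(open_pairs))) {
    p <- open_pairs[r, ]
    hit <- which(inside & p > 0)
    partners <- p[hit]
    p[hit] <- 0L
    p[partners] <- 0L
    open_pairs[r, ] <- p
  }
  unfolded <- cpp_energy_batch(codes, open_pairs, unclass(model), g)
  vals <- unfolded - folded
  mfe <- mfe_fold(ensemble$sequence, model, pseudo, profile)
  list(mean = mean(vals), sd = pop_sd(vals), skew = pop_skew(vals),
       kurtosis = pop_kurtosis(vals),
       mfe_delta_g = delta_g_unfold(mfe, interval, model, pseudo, profile),
       n = length(vals), values = vals)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
pop_skew <- function(x) {
  s <- pop_sd(x)
  if (s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}
pop_kurtosis <- function(x) {
  s <- pop_sd(x)
  if (s == 0) return(0)
  mean((x - mean(x))^4) / s^4 - 3
}

#' Count spliceosome footprint nucleotides from coordinates
#'
#' Reads a PDB coordinate file, takes the pre-mRNA chain, and counts
#' resolved nucleotide residues upstream of (residue number <= junction,
#' exonic) and downstream of (> junction, intronic) the declared exon-intron
#' junction.  Residues with at least one atom record count; unresolved
#' residues do not.
#'
#' @param path PDB file path.
#' @param chain_id chain identifier of the pre-mRNA chain.
#' @param junction_residue residue number of the last exonic nucleotide.
#' @return integer vector `c(n_exonic, n_intronic)`.
#' @export
count_footprint_from_coordinates <- function(path, chain_id,
                                             junction_residue) {
  if (!file.exists(path)) stop("coordinate file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) NULL)  # bio3d rejects atom-less files
  if (is.null(pdb) || !nrow(pdb$atom))       # treat them as an empty chain
    return(c(n_exonic = 0L, n_intronic = 0L))
  at <- pdb$atom[pdb$atom$chain == chain_id, , drop = FALSE]
  if (!nrow(at)) stop("chain '", chain_id, "' not found in ", path)
  nt <- at[at$resid %in% c("A", "C", "G", "U", "RA", "RC", "RG", "RU"), ,
           drop = FALSE]
  resno <- unique(nt$resno)
  c(n_exonic = sum(resno <= junction_residue),
    n_intronic = sum(resno > junction_residue))
}

#' Exon-independence folding scan
#'
#' Emulates co-transcriptional availability of downstream sequence: folds
#' the exon alone, then repeatedly extends by one downstream nucleotide and
#' refolds (MFE, restricted to the reactivities of the folded positions),
#' reporting at each step the fraction of base pairs with both ends inside
#' the exon interval.  A fold with no pairs reports 1 by convention and is
#' flagged.
#'
#' @param js junction sequence.
#' @param exon_interval integer `c(start, end)` of the exon.
#' @param profile optional reactivity profile.
#' @param model an [energy_model()].
#' @param pseudo optional [pseudo_energy_model()].
#' @param max_extension cap on the number of added nucleotides (default: to
#'   the end of the sequence).
#' @return data.frame with columns `extension`, `n_pairs`,
#'   `n_intra_pairs`, `fraction_intra`, `empty`.
#' @export
exon_independence_scan <- function(js, exon_interval, profile = NULL,
                                   model = energy_model(), pseudo = NULL,
                                   max_extension = NULL) {
  n <- nchar(js$sequence)
  stopifnot(exon_interval[1] >= 1, exon_interval[2] <= n)
  if (is.null(max_extension)) max_extension <- n - exon_interval[2]
  ex_len <- exon_interval[2] - exon_interval[1] + 1
  out <- vector("list", max_extension + 1)
  for (k in 0:max_extension) {
    end <- exon_interval[2] + k
    subseq <- substr(js$sequence, exon_interval[1], end)
    subprof <- if (!is.null(profile)) {
      sp <- profile[profile$position >= exon_interval[1] &
                      profile$position <= end, , drop = FALSE]
      sp$position <- sp$position - exon_interval[1] + 1L
      sp
    } else NULL
    ps <- if (is.null(pseudo) || is.null(subprof)) NULL else pseudo
    mfe <- mfe_fold(subseq, model, ps, subprof)
    pl <- pair_list(mfe)
    npairs <- nrow(pl)
    intra <- if (npairs) sum(pl[, 2] <= ex_len) else 0L
    out[[k + 1]] <- data.frame(extension = k, n_pairs = npairs,
                               n_intra_pairs = intra,
                               fraction_intra = if (npairs) intra / npairs
                                                else 1,
                               empty = npairs == 0)
  }
  do.call(rbind, out)
}
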