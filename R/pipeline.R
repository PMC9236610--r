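#' Parse and format junction-relative mutation identifiers
#'
#' Mutations are named relative to the exon-intron junction: intronic
#' positions +1, +2, ... count from the first intron base; exonic positions
#' -1, -2, ... count backward from the last exon base (so "+19C>G" is a C-
#' to-G substitution 19 nt into the intron).  Compensatory double mutations
#' join two substitutions with ";".
#'
#' @param id mutation identifier string.
#' @return `parse_mutation`: a `mutation_spec` — list with `id` and `subs`,
#'   a data.frame of (position, ref, alt) junction-relative substitutions.
#' @export
parse_mutation <- function(id) {
  parts <- strsplit(gsub("\\s", "", id), "[;,]")[[1]]
  m <- regmatches(parts, regexec("^([+-])(\\d+)([ACGUT])>([ACGUT])$", parts))
  bad <- vapply(m, length, integer(1)) != 5
  if (any(bad)) stop("malformed mutation id '", id, "'")
  subs <- do.call(rbind, lapply(m, function(g) {
    pos <- as.integer(g[3]) * if (g[2] == "-") -1L else 1L
    if (pos == 0L) stop("position 0 is not a junction-relative position")
    data.frame(position = pos, ref = chartr("T", "U", g[4]),
               alt = chartr("T", "U", g[5]), stringsAsFactors = FALSE)
  }))
  structure(list(id = format_mutation_subs(subs), subs = subs),
            class = "mutation_spec")
}

format_mutation_subs <- function(subs) {
  paste(sprintf("%s%d%s>%s", ifelse(subs$position > 0, "+", "-"),
                abs(subs$position), subs$ref, subs$alt), collapse = ";")
}

#' @rdname parse_mutation
#' @param spec a `mutation_spec`.
#' @export
format_mutation <- function(spec) spec$id

# junction-relative -> absolute 1-based position
abs_position <- function(rel, off) {
  ifelse(rel > 0, off + rel, off + rel + 1L)
}

#' Apply a mutation to the wild type and mask its reactivities
#'
#' Edits the sequence and returns the wild-type reactivity profile with the
#' value at every mutated position set to the no-data sentinel (wild-type
#' probing data restrain the mutant ensemble everywhere except at the
#' mutated sites, where they no longer apply).  All other profile entries
#' are untouched.
#'
#' @param js a `junction_sequence`.
#' @param spec a `mutation_spec` (or id string).
#' @param profile wild-type reactivity profile.
#' @return list with `sequence` (mutant string) and `profile` (masked).
#' @export
apply_mutation <- function(js, spec, profile = NULL) {
  if (is.character(spec)) spec <- parse_mutation(spec)
  chars <- strsplit(js$sequence, "")[[1]]
  off <- js$junction_offset
  pos <- abs_position(spec$subs$position, off)
  if (any(pos < 1 | pos > length(chars)))
    stop("mutation position outside the sequence")
  mism <- chars[pos] != spec$subs$ref
  if (any(mism))
    stop("reference base mismatch at ",
         paste(spec$subs$position[mism], collapse = ", "),
         " (wild type has ", paste(chars[pos][mism], collapse = ", "), ")")
  chars[pos] <- spec$subs$alt
  masked <- profile
  if (!is.null(masked)) {
    hit <- masked$position %in% pos
    masked$reactivity[hit] <- NO_DATA
    masked$se[hit] <- NA_real_
  }
  list(sequence = paste(chars, collapse = ""), profile = masked,
       positions = pos)
}

#' Pipeline configuration
#'
#' Bundles everything a variant-to-PSI run needs: the wild-type junction
#' sequence, its folding-ready reactivity profile, the energy and
#' pseudo-energy models, SRE and RBP PWM sets, the donor-site scorer, the
#' footprint stage whose unfolding energy is modeled (default Bact, the
#' stage that best predicts exon inclusion), the ensemble size, and the
#' base seed (variant v uses seed + v so ensembles are independent but
#' reproducible).
#'
#' @param wild_type a `junction_sequence`.
#' @param profile folding-ready reactivity profile.
#' @param model an [energy_model()].
#' @param pseudo a [pseudo_energy_model()] or NULL.
#' @param pwms list of SRE `motif_pwm`.
#' @param rbp_pwms list of RBP `motif_pwm`.
#' @param ss_model a `splice_site_model`.
#' @param stage footprint stage ("PreB", "B", "PreBact", "Bact",
#'   "splice_site").
#' @param n_samples ensemble size (study default 1000).
#' @param seed base seed.
#' @param reading_frame codon phase of the first exonic position in the
#'   modeled window (0, 1, or 2), used to call synonymous vs
#'   non-synonymous for unlabeled variants.
#' @export
pipeline_config <- function(wild_type, profile, model = energy_model(),
                            pseudo = NULL, pwms = list(),
                            rbp_pwms = list(),
                            ss_model = splice_site_model_default(),
                            stage = "Bact", n_samples = 1000, seed = 1L,
                            reading_frame = 0L) {
  stopifnot(n_samples >= 1)
  structure(list(wild_type = wild_type, profile = profile, model = model,
                 pseudo = pseudo, pwms = pwms, rbp_pwms = rbp_pwms,
                 ss_model = ss_model, stage = stage,
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 reading_frame = as.integer(reading_frame)),
            class = "pipeline_config")
}

# features for a set of mutation ids (category flags from labels)
variant_features <- function(config, ids, categories = NULL) {
  wt <- config$wild_type
  region <- footprint_region(config$stage, wt)
  interval <- attr(region, "interval")
  rows <- vector("list", length(ids))
  for (v in seq_along(ids)) {
    app <- apply_mutation(wt, ids[[v]], config$profile)
    ens <- sample_structures(app$sequence, config$model, config$pseudo,
                             app$profile, n = config$n_samples,
                             seed = config$seed + v)
    st <- ensemble_unfolding_stats(ens, interval, config$model,
                                   config$pseudo, app$profile)
    ds <- delta_strength(config$pwms, wt, app$sequence)
    dss <- splice_site_delta(wt, app$sequence, config$ss_model)
    rb <- if (length(config$rbp_pwms))
      rbp_delta(config$rbp_pwms, wt, app$sequence)
    else list(Ex = 0, In = 0)
    cat_v <- if (is.null(categories)) infer_category(config, ids[[v]])
             else categories[v]
    # compensatory doubles carry the flags of their component substitutions
    if (identical(cat_v, "compensatory"))
      cat_v <- infer_category(config, ids[[v]])
    flags <- category_flags(cat_v)
    rows[[v]] <- data.frame(
      mean_dg = st$mean, sd_dg = st$sd, skew_dg = st$skew,
      kurt_dg = st$kurtosis, mfe_dg = st$mfe_delta_g,
      dss = dss, enhancer = ds$enhancer, silencer = ds$silencer,
      rbp_ex = rb$Ex, rbp_in = rb$In,
      is_non_synonymous = flags[1], is_synonymous = flags[2],
      is_intronic = flags[3])
  }
  do.call(rbind, rows)
}

category_flags <- function(category) {
  switch(category,
         non_synonymous = c(1L, 0L, 0L),
         synonymous = c(0L, 1L, 0L),
         intronic = c(0L, 0L, 1L),
         wt_like = c(0L, 0L, 0L),
         stop("unknown category '", category, "'"))
}

# synonymous / non-synonymous / intronic call from codon position
infer_category <- function(config, id) {
  spec <- if (is.character(id)) parse_mutation(id) else id
  off <- config$wild_type$junction_offset
  pos <- abs_position(spec$subs$position, off)
  if (all(pos > off)) return("intronic")
  app <- apply_mutation(config$wild_type, spec)
  exonic <- pos[pos <= off]
  frame <- config$reading_frame
  wt_seq <- config$wild_type$sequence
  for (p in exonic) {
    codon_start <- p - ((p - 1 + frame) %% 3)
    if (codon_start < 1 || codon_start + 2 > nchar(wt_seq)) next
    wt_codon <- substr(wt_seq, codon_start, codon_start + 2)
    mut_codon <- substr(app$sequence, codon_start, codon_start + 2)
    if (GENETIC_CODE_RNA[[wt_codon]] != GENETIC_CODE_RNA[[mut_codon]])
      return("non_synonymous")
  }
  "synonymous"
}

GENETIC_CODE_RNA <- local({
  b <- c("U", "C", "A", "G")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSRRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(unlist(aas), codons)
})

#' End-to-end variant PSI prediction
#'
#' For each variant: build the mutant sequence with masked wild-type
#' reactivities, sample its Boltzmann ensemble, compute footprint unfolding
#' statistics and motif Delta strengths, assemble the feature vector, then
#' fit the requested beta-regression formula (when the panel carries
#' experimental PSI) and/or predict PSI.  Fully deterministic for a fixed
#' config seed.  Per-variant failures are recorded and the run continues.
#'
#' @param config a [pipeline_config()].
#' @param panel either a character vector of mutation ids or a data.frame
#'   with columns `id`, optionally `category` and `psi`.
#' @param formula_id beta-regression formula (default "interactive").
#' @param fit existing `beta_fit` to predict with (skips fitting).
#' @return list with `features` (per-variant data.frame incl. predictions),
#'   `fit` (or NULL), `errors` (named list of per-variant failures).
#' @export
run_variant_prediction <- function(config, panel,
                                   formula_id = "interactive", fit = NULL) {
  if (is.character(panel))
    panel <- data.frame(id = panel, stringsAsFactors = FALSE)
  ids <- panel$id
  categories <- if ("category" %in% names(panel)) panel$category else NULL
  errors <- list()
  feats_list <- vector("list", length(ids))
  for (v in seq_along(ids)) {
    res <- tryCatch(
      variant_features(config_subset_seed(config, v), list(ids[[v]]),
                       if (is.null(categories)) NULL else categories[v]),
      error = function(e) e)
    if (inherits(res, "error")) errors[[ids[[v]]]] <- conditionMessage(res)
    else feats_list[[v]] <- res
  }
  ok <- !vapply(feats_list, is.null, logical(1))
  feats <- do.call(rbind, feats_list[ok])
  out <- cbind(panel[ok, , drop = FALSE], feats)
  if (is.null(fit) && "psi" %in% names(out))
    fit <- fit_beta_regression(out, formula_id)
  if (!is.null(fit)) out$psi_predicted <- predict_psi(fit, out)
  list(features = out, fit = fit, errors = errors)
}

# per-variant deterministic seeding inside run_variant_prediction
config_subset_seed <- function(config, v) {
  config$seed <- config$seed + v - 1L
  config
}

#' In silico saturation mutagenesis
#'
#' Predicts PSI for every possible single substitution (3 per position) in a
#' window around the junction — a 100-nt window yields 300 mutants — and
#' summarizes per position the mean predicted PSI and the mean change in
#' ensemble-mean unfolding energy relative to wild type.
#'
#' @param config a [pipeline_config()].
#' @param window integer `c(start, end)` of absolute positions, or a
#'   `junction_region`.
#' @param fit fitted `beta_fit` used for prediction (train it first on a
#'   labeled panel).
#' @return list with `predictions` (one row per mutant) and `per_position`
#'   (position, mean_psi, mean_ddg).
#' @export
saturation_mutagenesis <- function(config, window, fit) {
  wt <- config$wild_type
  if (inherits(window, "junction_region"))
    window <- resolve_region(window, wt)
  ids <- saturation_ids(wt, window)
  off <- wt$junction_offset
  # wild-type ensemble stats for the ddG reference
  region <- footprint_region(config$stage, wt)
  interval <- attr(region, "interval")
  wt_ens <- sample_structures(wt$sequence, config$model, config$pseudo,
                              config$profile, n = config$n_samples,
                              seed = config$seed)
  wt_stats <- ensemble_unfolding_stats(wt_ens, interval, config$model,
                                       config$pseudo, config$profile)
  res <- run_variant_prediction(config, ids, fit = fit)
  pred <- res$features
  pred$position <- abs_position(
    vapply(pred$id, function(i) parse_mutation(i)$subs$position[1],
           integer(1)), off)
  pred$ddg_mean <- pred$mean_dg - wt_stats$mean
  per_position <- do.call(rbind, lapply(split(pred, pred$position),
    function(d) data.frame(position = d$position[1],
                           mean_psi = mean(d$psi_predicted),
                           mean_ddg = mean(d$ddg_mean))))
  rownames(per_position) <- NULL
  list(predictions = pred, per_position = per_position,
       wt_stats = wt_stats, errors = res$errors)
}

#' @rdname saturation_mutagenesis
#' @param wt a `junction_sequence`.
#' @return `saturation_ids`: character vector of the 3 * window-width
#'   distinct mutation ids.
#' @export
saturation_ids <- function(wt, window) {
  off <- wt$junction_offset
  chars <- strsplit(wt$sequence, "")[[1]]
  bases <- c("A", "C", "G", "U")
  unlist(lapply(window[1]:window[2], function(p)
    vapply(setdiff(bases, chars[p]), function(alt)
      paste0(pos_label(p, off), chars[p], ">", alt), character(1))))
}

#' PSI from splicing-gel band intensities
#'
#' Per replicate, PSI = I(4R) / (I(4R) + I(3R)) — the fraction of
#' transcripts including the alternative exon (4R isoform band over both
#' isoform bands); returns the mean and standard error over replicates.
#'
#' @param bands data.frame with columns `intensity_4r`, `intensity_3r`
#'   (arbitrary units >= 0), one row per replicate.
#' @return list with `psi` (per replicate), `mean`, `se`.
#' @export
gel_psi <- function(bands) {
  tot <- bands$intensity_4r + bands$intensity_3r
  if (any(tot <= 0)) stop("PSI undefined: replicate with both bands zero")
  psi <- bands$intensity_4r / tot
  list(psi = psi, mean = mean(psi),
       se = if (length(psi) > 1) sd(psi) / sqrt(length(psi)) else NA_real_)
}
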