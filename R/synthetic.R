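#' Generate a junction sequence with a planted hairpin
#'
#' Produces a random RNA sequence carrying one hairpin of `hairpin_arm`
#' complementary pairs whose span straddles the declared exon-intron
#' junction (emulating the strongly structured hairpin observed at the
#' studied 5' splice site).  The study amplicon is 234 nt; the default
#' fixture emulates it with the junction at offset 93.
#'
#' @param length sequence length (>= 2 * hairpin_arm + 7).
#' @param junction_offset 1-based index of the last exonic nucleotide.
#' @param hairpin_arm number of planted base pairs.
#' @param seed integer seed (one RNG stream per call; the global RNG is
#'   untouched).
#' @param loop_len hairpin loop length (default 4).
#' @return a junction sequence: list with `sequence`, `junction_offset`,
#'   and `true_structure` (a `secondary_structure` holding the planted
#'   hairpin), class `junction_sequence`.
#' @export
gen_junction_sequence <- function(length, junction_offset, hairpin_arm,
                                  seed = 1L, loop_len = 4L) {
  length <- as.integer(length)
  junction_offset <- as.integer(junction_offset)
  hairpin_arm <- as.integer(hairpin_arm)
  span <- 2L * hairpin_arm + loop_len
  if (length < 2L * hairpin_arm + 7L)
    stop("length must be at least 2 * hairpin_arm + 7")
  if (junction_offset < 1L || junction_offset >= length)
    stop("junction offset must satisfy 1 <= offset < length")
  start <- junction_offset - span %/% 2L + 1L
  start <- max(1L, min(start, length - span + 1L))
  if (junction_offset < start || junction_offset >= start + span)
    stop("junction cannot be placed inside the hairpin span")
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "U")
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    s <- sample(bases, length, replace = TRUE)
    left <- start:(start + hairpin_arm - 1L)
    right <- (start + span - 1L):(start + hairpin_arm + loop_len)
    arm <- sample(bases, hairpin_arm, replace = TRUE, prob = c(.2, .3, .3, .2))
    s[left] <- arm
    s[right] <- comp[arm]
    pairs <- integer(length)
    pairs[left] <- right
    pairs[right] <- left
    sequence <- paste(s, collapse = "")
    structure(list(sequence = sequence,
                   junction_offset = junction_offset,
                   true_structure = secondary_structure(sequence, pairs)),
              class = "junction_sequence")
  })
}

#' @export
print.junction_sequence <- function(x, ...) {
  cat("junction_sequence:", nchar(x$sequence), "nt, junction after position",
      x$junction_offset, "\n")
  invisible(x)
}

#' Reactivity simulation parameters
#'
#' Context means must be ordered unpaired > helix-end > stacked > 0; draws
#' are gamma with shape `dispersion` and context-specific mean.  Defaults
#' (0.8 / 0.2 / 0.05, shape 2) reproduce the qualitative ordering of
#' probing reactivities by pairing context.
#'
#' @param unpaired_mean,helix_end_mean,paired_mean context means.
#' @param dispersion gamma shape.
#' @param seed integer seed.
#' @export
reactivity_sim_params <- function(unpaired_mean = 0.8, helix_end_mean = 0.2,
                                  paired_mean = 0.05, dispersion = 2,
                                  seed = 1L) {
  stopifnot(unpaired_mean > helix_end_mean, helix_end_mean > paired_mean,
            paired_mean > 0, dispersion > 0)
  list(unpaired_mean = unpaired_mean, helix_end_mean = helix_end_mean,
       paired_mean = paired_mean, dispersion = dispersion,
       seed = as.integer(seed))
}

#' Simulate per-nucleotide reactivities from a known structure
#'
#' Each nucleotide draws its raw reactivity from the gamma distribution of
#' its pairing context (unpaired / helix-end / stacked); values are
#' nonnegative.  This is the inverse of context calibration: high
#' reactivities mark less-structured regions.
#'
#' @param structure a `secondary_structure`.
#' @param params from [reactivity_sim_params()].
#' @return reactivity profile data.frame (position, base, reactivity, se).
#' @export
simulate_reactivities <- function(structure, params = reactivity_sim_params()) {
  ctx <- classify_context(structure)
  n <- length(ctx)
  means <- c(unpaired = params$unpaired_mean,
             helix_end = params$helix_end_mean,
             stacked = params$paired_mean)[ctx]
  shape <- params$dispersion
  vals <- withr::with_seed(params$seed,
    rgamma(n, shape = shape, scale = means / shape))
  data.frame(position = seq_len(n),
             base = strsplit(structure$sequence, "")[[1]],
             reactivity = vals,
             se = vals / sqrt(shape),
             stringsAsFactors = FALSE)
}

#' Simulate a ShapeMapper-style mutation-rate table
#'
#' Treated rate = background + `rate_scale` * reactivity (clamped to
#' `[0, 0.999]`), untreated rate = background, with binomial counting noise
#' at the given read depth.  With `depth = Inf` the analytic rates are
#' returned noise-free, so [compute_raw_reactivity()] recovers
#' `rate_scale * reactivity` exactly (the default scale 1 expects raw-scale
#' reactivities, i.e., mutation-rate differences).
#'
#' @param profile reactivity profile.
#' @param depth reads per position (Inf = analytic limit).
#' @param background_rate untreated mutation rate in `[0, 1)`.
#' @param seed integer seed.
#' @param rate_scale reactivity-to-rate scale (default 1).
#' @return mutation-rate table data.frame.
#' @export
simulate_profile_table <- function(profile, depth, background_rate = 0.005,
                                   seed = 1L, rate_scale = 1) {
  stopifnot(depth > 0, background_rate >= 0, background_rate < 1)
  r <- pmax(profile$reactivity, 0)
  r[profile$reactivity == NO_DATA] <- 0
  p_s <- pmin(pmax(background_rate + rate_scale * r, 0), 0.999)
  p_u <- rep(background_rate, length(r))
  n <- length(r)
  if (is.finite(depth)) {
    depth <- as.integer(depth)
    rates <- withr::with_seed(seed, list(
      s = rbinom(n, depth, p_s) / depth,
      u = rbinom(n, depth, p_u) / depth))
    p_s <- rates$s
    p_u <- rates$u
    d <- depth
  } else d <- NA_real_
  data.frame(position = profile$position, base = profile$base,
             mutr_s = p_s, mutr_u = p_u,
             depth_s = if (is.na(d)) 1e12 else d,
             depth_u = if (is.na(d)) 1e12 else d,
             stringsAsFactors = FALSE)
}

#' Synthetic mutation panel specification
#'
#' @param true_coefficients coefficients on the logit scale for the
#'   `interactive` design (intercept, four gated structure moments, three
#'   gated SRE terms).  The defaults are calibrated to the typical spread
#'   of each feature over mutation panels on the default fixtures (the
#'   ensemble kurtosis shift, for instance, is an order of magnitude wider
#'   than the mean shift), so that simulated PSI spans the unit interval
#'   without piling up on the boundaries.
#' @param precision_phi Beta precision (> 0).
#' @param n_mutations panel size (the study panel holds 47 mutations).
#' @param category_mix proportions over non-synonymous / synonymous /
#'   intronic / compensatory; must sum to 1.
#' @param seed integer seed.
#' @export
synthetic_panel_spec <- function(true_coefficients = c(0.4, -0.12, -0.5,
                                                       0.05, 0.004, 0.25,
                                                       -0.25, 0.6),
                                 precision_phi = 50, n_mutations = 47,
                                 category_mix = c(non_synonymous = 0.30,
                                                  synonymous = 0.25,
                                                  intronic = 0.35,
                                                  compensatory = 0.10),
                                 seed = 1L) {
  stopifnot(precision_phi > 0, abs(sum(category_mix) - 1) < 1e-8,
            length(true_coefficients) == 8)
  list(true_coefficients = true_coefficients,
       precision_phi = precision_phi,
       n_mutations = as.integer(n_mutations),
       category_mix = category_mix, seed = as.integer(seed))
}

#' Simulate a mutation panel with Beta-distributed PSI
#'
#' Draws random single-nucleotide substitutions around the junction
#' (positions inside the 9-mer donor site are oversampled eightfold so the
#' donor-strength feature varies, mirroring how disease panels concentrate
#' near the splice site), computes every mutation's features by running the
#' real pipeline on the wild-type fixture (ensemble unfolding statistics
#' with masked reactivities, SRE/RBP Delta strengths, category flags; the
#' unfolding statistics are reported as changes relative to the wild-type
#' ensemble, keeping the generating model invariant to fixture length), sets
#' the mean PSI by inverse-logit of the `interactive`-design linear
#' predictor under the true coefficients, and draws observed PSI from
#' Beta(mu phi, (1 - mu) phi).  Category labels follow `category_mix`;
#' compensatory entries carry two substitutions.
#'
#' @param spec from [synthetic_panel_spec()].
#' @param wild_type a `junction_sequence`.
#' @param config optional [pipeline_config()]; by default one is assembled
#'   from the wild type's true structure (simulated reactivities, gamma
#'   contexts, bundled synthetic motifs).
#' @param n_samples ensemble size per mutation (default 100).
#' @return a mutation panel data.frame (id, category, psi, psi_mean,
#'   features) with the generating config in `attr(, "config")`.
#' @export
simulate_mutation_panel <- function(spec, wild_type, config = NULL,
                                    n_samples = 100) {
  if (is.null(config))
    config <- default_synthetic_config(wild_type, n_samples = n_samples,
                                       seed = spec$seed)
  off <- wild_type$junction_offset
  n <- nchar(wild_type$sequence)
  wt_chars <- strsplit(wild_type$sequence, "")[[1]]
  bases <- c("A", "C", "G", "U")
  cat_levels <- c("non_synonymous", "synonymous", "intronic", "compensatory")
  counts <- diff(round(cumsum(c(0, spec$category_mix)) * spec$n_mutations))
  categories <- rep(cat_levels, counts)
  length(categories) <- spec$n_mutations
  categories[is.na(categories)] <- "intronic"

  panel <- withr::with_seed(spec$seed, {
    exonic_pos <- seq_len(off)
    intronic_pos <- (off + 1):n
    wt_ss <- (off - 2):(off + 6)
    weight <- function(pos) ifelse(pos %in% wt_ss, 8, 1)
    draw_pos <- function(pool) sample(pool, 1, prob = weight(pool))
    specs <- character(spec$n_mutations)
    for (i in seq_len(spec$n_mutations)) {
      cat_i <- categories[i]
      pool <- switch(cat_i,
                     non_synonymous = exonic_pos, synonymous = exonic_pos,
                     intronic = intronic_pos, compensatory = intronic_pos)
      repeat {
        p1 <- draw_pos(pool)
        alt <- sample(setdiff(bases, wt_chars[p1]), 1)
        id <- paste0(pos_label(p1, off), wt_chars[p1], ">", alt)
        if (cat_i == "compensatory") {
          p2 <- draw_pos(setdiff(pool, p1))
          alt2 <- sample(setdiff(bases, wt_chars[p2]), 1)
          id <- paste(id, paste0(pos_label(p2, off), wt_chars[p2], ">", alt2),
                      sep = ";")
        }
        if (!id %in% specs) break
      }
      specs[i] <- id
    }
    specs
  })

  feats <- variant_features(config, panel, categories)
  # structure features are reported as changes relative to the wild-type
  # ensemble, so the true coefficients act on mutation-induced shifts and
  # keep the implied PSI range realistic at any fixture length
  wt_stats <- wildtype_unfolding_stats(config)
  for (col in c("mean_dg", "sd_dg", "skew_dg", "kurt_dg", "mfe_dg"))
    feats[[col]] <- feats[[col]] - wt_stats[[col]]
  X <- psi_design_matrix("interactive", feats)
  eta <- drop(X %*% spec$true_coefficients)
  mu <- plogis(eta)
  psi <- if (is.finite(spec$precision_phi)) {
    withr::with_seed(spec$seed + 1L,
      rbeta(length(mu), mu * spec$precision_phi,
            (1 - mu) * spec$precision_phi))
  } else mu  # degenerate Beta: observed PSI equals the mean
  # complete splicing outcomes are recorded at 0.02 / 0.98, not exactly 0/1
  psi[psi == 0] <- 0.02
  psi[psi == 1] <- 0.98
  out <- cbind(data.frame(id = panel, category = categories, psi = psi,
                          psi_mean = mu, stringsAsFactors = FALSE),
               feats)
  attr(out, "config") <- config
  out
}

# unfolding statistics of the wild-type ensemble under a config
wildtype_unfolding_stats <- function(config) {
  wt <- config$wild_type
  region <- footprint_region(config$stage, wt)
  ens <- sample_structures(wt$sequence, config$model, config$pseudo,
                           config$profile, n = config$n_samples,
                           seed = config$seed)
  st <- ensemble_unfolding_stats(ens, attr(region, "interval"),
                                 config$model, config$pseudo,
                                 config$profile)
  data.frame(mean_dg = st$mean, sd_dg = st$sd, skew_dg = st$skew,
             kurt_dg = st$kurtosis, mfe_dg = st$mfe_delta_g)
}

pos_label <- function(pos, off) {
  if (pos <= off) paste0("-", off - pos + 1) else paste0("+", pos - off)
}

#' Default pipeline configuration for a synthetic wild type
#'
#' Simulated reactivities from the planted structure, gamma context
#' distributions at the simulation means, the bundled synthetic motif set,
#' and the default donor model and energy model.
#'
#' @param wild_type a `junction_sequence` with `true_structure`.
#' @param n_samples ensemble size.
#' @param seed integer seed.
#' @param sim_params reactivity simulation parameters.
#' @return a [pipeline_config()].
#' @export
default_synthetic_config <- function(wild_type, n_samples = 100, seed = 1L,
                                     sim_params = reactivity_sim_params(
                                       seed = seed)) {
  profile <- simulate_reactivities(wild_type$true_structure, sim_params)
  contexts <- context_distributions_gamma(
    unpaired_mean = sim_params$unpaired_mean,
    helix_end_mean = sim_params$helix_end_mean,
    stacked_mean = sim_params$paired_mean,
    shape = sim_params$dispersion)
  motifs <- synthetic_motif_set()
  pipeline_config(
    wild_type = wild_type,
    profile = prepare_for_folding(normalize_raw_or_pass(profile)),
    model = energy_model(),
    pseudo = pseudo_energy_model(contexts),
    pwms = motifs[vapply(motifs, function(p)
      p$category %in% c("ESE", "ESS", "ISE", "ISS"), logical(1))],
    rbp_pwms = motifs[vapply(motifs, function(p)
      startsWith(p$category, "RBP"), logical(1))],
    ss_model = splice_site_model_default(),
    stage = "splice_site",
    n_samples = n_samples,
    seed = seed)
}

# normalize when enough values per base, otherwise pass through raw
normalize_raw_or_pass <- function(profile) {
  enough <- all(table(factor(profile$base,
                             levels = c("A", "C", "G", "U"))) >= 10)
  if (enough) suppressWarnings(normalize_per_base(profile)) else profile
}

#' Write a synthetic spliceosome-complex coordinate fixture
#'
#' Emits a minimal PDB file holding one RNA chain with `n_exonic` residues
#' upstream and `n_intronic` residues downstream of the declared junction
#' residue (one phosphorus atom per residue).  The fixture is synthetic: it
#' exercises footprint counting, not geometry.
#'
#' @param n_exonic,n_intronic residue counts (>= 0).
#' @param path output file (default a tempfile).
#' @param chain_id chain identifier (default "R").
#' @return list with `path`, `chain_id`, `junction_residue` (= n_exonic).
#' @export
make_synthetic_coordinates <- function(n_exonic, n_intronic,
                                       path = tempfile(fileext = ".pdb"),
                                       chain_id = "R") {
  stopifnot(n_exonic >= 0, n_intronic >= 0)
  total <- n_exonic + n_intronic
  con <- file(path, "w")
  writeLines("REMARK synthetic spliceosome pre-mRNA fixture", con)
  if (total > 0) {
    bases <- rep(c("A", "C", "G", "U"), length.out = total)
    for (i in seq_len(total)) {
      writeLines(sprintf(
        "ATOM  %5d P    %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           P",
        i, bases[i], chain_id, i, i * 6.0, 0.0, 0.0), con)
    }
  }
  writeLines("END", con)
  close(con)
  list(path = path, chain_id = chain_id,
       junction_residue = as.integer(n_exonic))
}
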