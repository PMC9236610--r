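#' Reactivity profiles from mutation-rate tables
#'
#' DMS-MaP chemical probing is read out as per-nucleotide reverse-
#' transcription mutation rates.  The raw reactivity of nucleotide i is the
#' background-subtracted rate
#' \deqn{R_i = mutr_S - mutr_U}
#' where `mutr_s` is the rate in the reagent-treated sample and `mutr_u` in
#' the untreated control.  Negative values are retained.  Standard errors are
#' propagated from the binomial rate SEs (square root of summed variances).
#'
#' @param table mutation-rate table: data.frame with columns `position`,
#'   `base`, `mutr_s`, `mutr_u`, `depth_s`, `depth_u` (see
#'   [read_profile_table()]).
#' @return a reactivity profile: data.frame with columns `position`, `base`,
#'   `reactivity`, `se`.  The no-data sentinel is -999.
#' @export
compute_raw_reactivity <- function(table) {
  validate_rate_table(table)
  se <- sqrt(table$mutr_s * (1 - table$mutr_s) / pmax(table$depth_s, 1) +
             table$mutr_u * (1 - table$mutr_u) / pmax(table$depth_u, 1))
  data.frame(position = table$position, base = table$base,
             reactivity = table$mutr_s - table$mutr_u, se = se,
             stringsAsFactors = FALSE)
}

NO_DATA <- -999

validate_rate_table <- function(table) {
  req <- c("position", "base", "mutr_s", "mutr_u", "depth_s", "depth_u")
  miss <- setdiff(req, names(table))
  if (length(miss)) stop("mutation-rate table lacks columns: ",
                         paste(miss, collapse = ", "))
  lens <- vapply(table[req], length, integer(1))
  if (length(unique(lens)) != 1) stop("malformed table: ragged columns")
  if (any(diff(table$position) <= 0))
    stop("positions must be strictly increasing")
  rates <- c(table$mutr_s, table$mutr_u)
  if (any(rates < 0 | rates > 1, na.rm = TRUE))
    stop("mutation rates must lie in [0, 1]")
  invisible(table)
}

#' Per-base-type reactivity normalization
#'
#' For each nucleotide type (A, C, G, U) separately: reactivities are divided
#' by the mean of the top 10% of values remaining after the most reactive 2%
#' are removed (ranks on non-sentinel values of that type, counts rounded
#' half-up).  After normalization the mean of the qualifying top decile is
#' exactly 1.  In `visualization_mode` the G and U profiles are additionally
#' rescaled so that their maximum is 0.1, matching how reactivity figures
#' display bases the reagent barely probes.
#'
#' A base type with fewer than 10 non-sentinel values is emitted as sentinel
#' with a warning.
#'
#' @param raw reactivity profile from [compute_raw_reactivity()].
#' @param visualization_mode logical.
#' @return normalized reactivity profile; normalization factors in
#'   `attr(, "norm_factors")`.
#' @export
normalize_per_base <- function(raw, visualization_mode = FALSE) {
  out <- raw
  factors <- c(A = NA_real_, C = NA_real_, G = NA_real_, U = NA_real_)
  for (b in names(factors)) {
    sel <- out$base == b & out$reactivity != NO_DATA
    vals <- out$reactivity[sel]
    if (length(vals) < 10) {
      if (any(out$base == b)) {
        warning("fewer than 10 usable values for base ", b,
                "; emitted as no-data")
        out$reactivity[out$base == b] <- NO_DATA
        out$se[out$base == b] <- NA_real_
      }
      next
    }
    f <- norm_factor(vals)
    factors[b] <- f
    out$reactivity[sel] <- vals / f
    out$se[sel] <- out$se[sel] / f
  }
  if (visualization_mode) {
    for (b in c("G", "U")) {
      sel <- out$base == b & out$reactivity != NO_DATA
      if (!any(sel)) next
      mx <- max(out$reactivity[sel])
      if (mx > 0) {
        out$reactivity[sel] <- out$reactivity[sel] / mx * 0.1
        out$se[sel] <- out$se[sel] / mx * 0.1
      }
    }
  }
  attr(out, "norm_factors") <- factors
  out
}

# top-decile mean after removing the most reactive 2% (round half-up)
norm_factor <- function(vals) {
  n <- length(vals)
  n_excl <- floor(0.02 * n + 0.5)
  n_top <- max(1, floor(0.10 * n + 0.5))
  sorted <- sort(vals, decreasing = TRUE)
  mean(sorted[(n_excl + 1):min(n, n_excl + n_top)])
}

#' Prepare a normalized profile for structure modeling
#'
#' DMS modifies the Watson-Crick face of A and C only, so G/U positions are
#' set to the no-data sentinel; reactivities above 5 are capped at 5 (the
#' same cap used when fitting context distributions); negative values are
#' floored at 0 for likelihood evaluation.
#'
#' @param profile normalized reactivity profile.
#' @return folding-ready profile.
#' @export
prepare_for_folding <- function(profile) {
  out <- profile
  gu <- out$base %in% c("G", "U")
  out$reactivity[gu] <- NO_DATA
  out$se[gu] <- NA_real_
  live <- out$reactivity != NO_DATA
  out$reactivity[live] <- pmin(pmax(out$reactivity[live], 0), 5)
  out
}

#' Calibrate context reactivity distributions against a reference structure
#'
#' Classifies every A/C nucleotide of the reference as unpaired, paired at a
#' helix end (a helix neighbor position is unpaired or out of range), or
#' stacked between two pairs, and fits a reactivity density per class from
#' the observed values capped at 5.  Densities are kernel estimates with
#' reflection at 0, truncated and renormalized on [0, cap].  If any class has
#' fewer than 20 observations the two paired classes are merged and the
#' result flagged.
#'
#' @param profile reactivity profile (A/C positions are used).
#' @param reference a `secondary_structure` covering the profile positions.
#' @param cap reactivity cap (default 5).
#' @param min_class minimum observations per class before merging.
#' @return a `context_distributions` object: densities `unpaired`,
#'   `helix_end`, `stacked`, class means, class proportions, `cap`, and
#'   `merged` flag.
#' @export
calibrate_context_distributions <- function(profile, reference, cap = 5,
                                            min_class = 20) {
  ctx <- classify_context(reference)
  keep <- profile$base %in% c("A", "C") & profile$reactivity != NO_DATA &
    profile$position <= length(reference$pairs)
  pos <- profile$position[keep]
  vals <- pmin(pmax(profile$reactivity[keep], 0), cap)
  cls <- ctx[pos]
  by_class <- split(vals, factor(cls, levels = c("unpaired", "helix_end",
                                                 "stacked")))
  merged <- any(vapply(by_class, length, integer(1)) < min_class)
  if (merged) {
    paired_vals <- c(by_class$helix_end, by_class$stacked)
    dens_p <- reflected_kde(paired_vals, cap)
    dists <- list(unpaired = reflected_kde(by_class$unpaired, cap),
                  helix_end = dens_p, stacked = dens_p)
    means <- c(unpaired = mean(by_class$unpaired),
               helix_end = mean(paired_vals), stacked = mean(paired_vals))
  } else {
    dists <- lapply(by_class, reflected_kde, cap = cap)
    means <- vapply(by_class, mean, numeric(1))
  }
  props <- vapply(by_class, length, integer(1)) / length(vals)
  structure(list(unpaired = dists$unpaired, helix_end = dists$helix_end,
                 stacked = dists$stacked, means = means, props = props,
                 cap = cap, merged = merged, kind = "kde"),
            class = "context_distributions")
}

# nucleotide pairing context: unpaired / helix_end / stacked
classify_context <- function(x) {
  p <- x$pairs
  n <- length(p)
  ctx <- rep("unpaired", n)
  for (i in which(p > 0)) {
    left_in <- i - 1 >= 1 && p[i - 1] > 0
    right_in <- i + 1 <= n && p[i + 1] > 0
    ctx[i] <- if (left_in && right_in) "stacked" else "helix_end"
  }
  ctx
}

# KDE with reflection at 0, truncated to [0, cap], renormalized
reflected_kde <- function(vals, cap) {
  if (!length(vals)) stop("no observations for density fit")
  d <- density(c(vals, -vals), from = 0, to = cap, n = 512)
  f <- approxfun(d$x, 2 * d$y, yleft = 2 * d$y[1], yright = 2 * d$y[512])
  grid <- seq(0, cap, length.out = 2048)
  mass <- sum(f(grid)) * (cap / (length(grid) - 1))
  function(x) f(pmin(pmax(x, 0), cap)) / mass
}

#' Parametric (gamma) context distributions
#'
#' Truncated-gamma reactivity likelihoods with a shared shape parameter and
#' context-specific means; the parametric form guarantees a monotone
#' paired/unpaired likelihood ratio in the reactivity, which the kernel
#' estimates from [calibrate_context_distributions()] do not.
#'
#' @param unpaired_mean,helix_end_mean,stacked_mean context means
#'   (reactivity units); must be strictly decreasing.
#' @param shape gamma shape parameter.
#' @param cap reactivity cap.
#' @return a `context_distributions` object.
#' @export
context_distributions_gamma <- function(unpaired_mean = 0.8,
                                        helix_end_mean = 0.2,
                                        stacked_mean = 0.05,
                                        shape = 2, cap = 5) {
  stopifnot(unpaired_mean > helix_end_mean, helix_end_mean > stacked_mean,
            stacked_mean > 0)
  tgamma <- function(mean) {
    scale <- mean / shape
    norm <- pgamma(cap, shape = shape, scale = scale)
    function(x) dgamma(pmin(pmax(x, 0), cap), shape = shape,
                       scale = scale) / norm
  }
  structure(list(unpaired = tgamma(unpaired_mean),
                 helix_end = tgamma(helix_end_mean),
                 stacked = tgamma(stacked_mean),
                 means = c(unpaired = unpaired_mean,
                           helix_end = helix_end_mean,
                           stacked = stacked_mean),
                 props = c(unpaired = 0.5, helix_end = 0.25, stacked = 0.25),
                 cap = cap, merged = FALSE, kind = "gamma"),
            class = "context_distributions")
}

#' Reactivity pseudo-energy model
#'
#' Converts context likelihoods into per-nucleotide folding restraints: a
#' paired nucleotide with reactivity r contributes
#' `-RT * log(P(r | paired) / P(r | unpaired))`, an unpaired or no-data
#' nucleotide contributes 0.  In the default two-context mode the helix-end
#' and stacked likelihoods are collapsed into a single paired likelihood by
#' mixture (weights from the calibrated class proportions); the three-context
#' mode is available for rescoring fixed structures via
#' [rescore_with_contexts()].
#'
#' @param contexts a `context_distributions` object.
#' @param mode "two_context" (used by the dynamic programs) or
#'   "three_context".
#' @return a `pseudo_energy_model`.
#' @export
pseudo_energy_model <- function(contexts, mode = c("two_context",
                                                   "three_context")) {
  mode <- match.arg(mode)
  stopifnot(inherits(contexts, "context_distributions"))
  structure(list(contexts = contexts, mode = mode),
            class = "pseudo_energy_model")
}

# per-position pseudo energies for paired nucleotides
pseudo_energies <- function(pseudo, profile, n, model) {
  g <- numeric(n)
  ctx <- pseudo$contexts
  wp <- ctx$props[c("helix_end", "stacked")]
  wp <- if (any(is.na(wp)) || sum(wp) == 0) c(0.5, 0.5) else wp / sum(wp)
  live <- profile$reactivity != NO_DATA & profile$position <= n &
    profile$base %in% c("A", "C")
  pos <- profile$position[live]
  r <- pmin(pmax(profile$reactivity[live], 0), ctx$cap)
  eps <- 1e-12
  f_pair <- wp[1] * ctx$helix_end(r) + wp[2] * ctx$stacked(r)
  f_un <- ctx$unpaired(r)
  g[pos] <- -model$RT * log(pmax(f_pair, eps) / pmax(f_un, eps))
  g
}

#' Rescore a fixed structure with three-context pseudo-energies
#'
#' Adds the context-resolved pseudo-energy (helix-end vs stacked resolved
#' from the structure itself) to the nearest-neighbor energy.
#'
#' @param x a `secondary_structure`.
#' @param model an [energy_model()].
#' @param contexts a `context_distributions`.
#' @param profile reactivity profile.
#' @return energy in kcal/mol.
#' @export
rescore_with_contexts <- function(x, model, contexts, profile) {
  base <- evaluate_energy(x, model)
  ctx <- classify_context(x)
  live <- profile$reactivity != NO_DATA & profile$base %in% c("A", "C") &
    profile$position <= length(x$pairs)
  pos <- profile$position[live]
  r <- pmin(pmax(profile$reactivity[live], 0), contexts$cap)
  eps <- 1e-12
  fl <- numeric(length(pos))
  for (k in seq_along(pos)) {
    ci <- ctx[pos[k]]
    if (ci == "unpaired") next
    f <- if (ci == "stacked") contexts$stacked(r[k]) else
      contexts$helix_end(r[k])
    fl[k] <- -model$RT * log(max(f, eps) / max(contexts$unpaired(r[k]), eps))
  }
  base + sum(fl)
}

#' AUC of reactivity as an unpaired-nucleotide classifier
#'
#' Assigns each A/C nucleotide 1 if unpaired in the reference and 0 if
#' paired, and computes the area under the ROC curve of reactivity as a score
#' for "unpaired" via the rank (Mann-Whitney) statistic, with ties averaged.
#'
#' @param profile reactivity profile.
#' @param reference a `secondary_structure`.
#' @return AUC in `[0, 1]`.
#' @export
reactivity_auc <- function(profile, reference) {
  keep <- profile$base %in% c("A", "C") & profile$reactivity != NO_DATA &
    profile$position <= length(reference$pairs)
  score <- profile$reactivity[keep]
  label <- as.integer(reference$pairs[profile$position[keep]] == 0)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: reference has a single pairing class")
  r <- rank(score)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Read / write .map reactivity files
#'
#' Four tab-separated columns: position, reactivity, SE, base; -999 marks
#' no data.
#'
#' @param path file path.
#' @return `read_map`: a reactivity profile data.frame.
#' @export
read_map <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  data.frame(position = as.integer(tab[[1]]), base = as.character(tab[[4]]),
             reactivity = as.numeric(tab[[2]]), se = as.numeric(tab[[3]]),
             stringsAsFactors = FALSE)
}

#' @rdname read_map
#' @param profile reactivity profile.
#' @export
write_map <- function(profile, path) {
  se <- ifelse(is.na(profile$se), 0, profile$se)
  write.table(data.frame(profile$position, profile$reactivity, se,
                         profile$base),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write ShapeMapper-style profile tables
#'
#' Tab-separated with a header; the columns consumed are `Nucleotide`,
#' `Sequence`, `Modified_rate`, `Untreated_rate`,
#' `Modified_effective_depth`, `Untreated_effective_depth`.
#'
#' @param path file path.
#' @return `read_profile_table`: a mutation-rate table data.frame with
#'   columns `position`, `base`, `mutr_s`, `mutr_u`, `depth_s`, `depth_u`.
#' @export
read_profile_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  data.frame(position = as.integer(tab$Nucleotide),
             base = chartr("T", "U", toupper(as.character(tab$Sequence))),
             mutr_s = as.numeric(tab$Modified_rate),
             mutr_u = as.numeric(tab$Untreated_rate),
             depth_s = as.numeric(tab$Modified_effective_depth),
             depth_u = as.numeric(tab$Untreated_effective_depth),
             stringsAsFactors = FALSE)
}

#' @rdname read_profile_table
#' @param table mutation-rate table.
#' @export
write_profile_table <- function(table, path) {
  out <- data.frame(Nucleotide = table$position, Sequence = table$base,
                    Modified_rate = table$mutr_s,
                    Untreated_rate = table$mutr_u,
                    Modified_effective_depth = table$depth_s,
                    Untreated_effective_depth = table$depth_u)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
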