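#' Digitize an ensemble into an element matrix
#'
#' Converts every member to its element string ([element_string()]) and
#' digitizes (f,t = 0, s = 1, h = 2, m = 3), giving an n-by-length integer
#' matrix (the study region yields 1000 x 234 per variant).
#'
#' @param ensemble a `structure_ensemble`.
#' @return integer matrix.
#' @export
digitize_ensemble <- function(ensemble) {
  n <- ensemble$n
  len <- nchar(ensemble$sequence)
  out <- matrix(0L, n, len)
  for (r in seq_len(n))
    out[r, ] <- element_string(ensemble_member(ensemble, r), digitize = TRUE)
  out
}

#' Embed and cluster structural ensembles
#'
#' Concatenates the digitized element matrices of several variants' ensembles
#' (e.g., 3 x 1000 structures x 234 nt), reduces them to two dimensions, and
#' clusters the embedded points with k-means (k-means++-style restarts via
#' `nstart`, fixed seed).  The default embedding is the first two principal
#' components of the digitized matrix (equivalent to classical
#' multidimensional scaling under Euclidean distance), a deterministic
#' library call.  Per-variant cluster occupancy fractions are returned; each
#' variant's occupancies sum to 1.
#'
#' @param ensembles named list of `structure_ensemble` sharing one length.
#' @param k number of clusters (default 5).
#' @param seed RNG seed for k-means restarts.
#' @param nstart k-means restarts (default 10).
#' @return list with `coords` (data.frame x, y, variant, cluster),
#'   `occupancy` (variants x clusters matrix), `centers`.
#' @export
embed_and_cluster <- function(ensembles, k = 5, seed = 1L, nstart = 10) {
  if (is.null(names(ensembles)))
    names(ensembles) <- paste0("variant", seq_along(ensembles))
  lens <- vapply(ensembles, function(e) nchar(e$sequence), integer(1))
  if (length(unique(lens)) != 1)
    stop("ensembles must share one sequence length")
  mats <- lapply(ensembles, digitize_ensemble)
  big <- do.call(rbind, mats)
  if (nrow(big) < k) stop("fewer structures than clusters")
  variant <- rep(names(ensembles), vapply(mats, nrow, integer(1)))
  keep <- which(apply(big, 2, var) > 0)
  emb <- if (length(keep) >= 2) {
    pc <- prcomp(big[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
    sc <- pc$x
    if (ncol(sc) >= 2) sc[, 1:2] else cbind(sc[, 1], 0)
  } else if (length(keep) == 1) {
    cbind(big[, keep] - mean(big[, keep]), 0)
  } else {
    matrix(0, nrow(big), 2)  # identical structures co-locate at the origin
  }
  km <- withr::with_seed(seed,
    kmeans(emb, centers = min(k, nrow(unique(emb))), nstart = nstart,
           iter.max = 100))
  coords <- data.frame(x = emb[, 1], y = emb[, 2], variant = variant,
                       cluster = km$cluster)
  nclus <- max(km$cluster)
  occupancy <- matrix(0, length(ensembles), nclus,
                      dimnames = list(names(ensembles), seq_len(nclus)))
  for (v in names(ensembles)) {
    tab <- tabulate(km$cluster[variant == v], nbins = nclus)
    occupancy[v, ] <- tab / sum(tab)
  }
  list(coords = coords, occupancy = occupancy, centers = km$centers)
}

#' Representative structure of a set of members
#'
#' Computes the most common element code at each nucleotide (plurality, ties
#' to the lower digit) and returns the member whose digitized string is
#' closest in Hamming distance to that consensus (ties to the earliest
#' member).  The result is always one of the input members.
#'
#' @param members list of `secondary_structure` of equal length.
#' @return a `secondary_structure` with attribute `consensus` (integer
#'   codes).
#' @export
representative_structure <- function(members) {
  stopifnot(length(members) >= 1)
  digs <- vapply(members, element_string, integer(nchar(members[[1]]$sequence)),
                 digitize = TRUE)
  digs <- t(digs)  # members x positions
  consensus <- apply(digs, 2, function(col) {
    tab <- tabulate(col + 1L, nbins = 4)
    which.max(tab) - 1L  # which.max returns the first (lowest digit) on ties
  })
  dists <- rowSums(digs != matrix(consensus, nrow(digs), ncol(digs),
                                  byrow = TRUE))
  best <- which.min(dists)
  out <- members[[best]]
  attr(out, "consensus") <- consensus
  attr(out, "member_index") <- best
  out
}

#' Normalize features and categorize mutations by supporting evidence
#'
#' For each feature (donor-strength change `dss`, `enhancer`, `silencer`,
#' and the ensemble-mean unfolding-energy change `mean_dg_delta`): non-zero
#' values are clipped at the 5th/95th percentiles of the non-zero values,
#' scaled by the maximum absolute value, the silencer and unfolding-energy
#' columns are inverted (so 1 always predicts inclusion), and all values are
#' mapped to `[0, 1]` around 0.5 (0.5 = no change).  Changed-flags record
#' whether a feature moved at all.  Mutations are hierarchically clustered
#' (average linkage, Euclidean) first on the changed-flags, then within each
#' cluster on the normalized values.  Each mutation is categorized by which
#' feature families agree in direction with its PSI (strict inequality
#' against 0.5): `both`, `SRE`, `structure`, or `neither`.
#'
#' @param panel data.frame with columns `id`, `psi`, `dss`, `enhancer`,
#'   `silencer`, `mean_dg_delta`.
#' @param n_flag_clusters clusters for the changed-flag stage (default 6).
#' @return data.frame with normalized feature columns (`*_norm`), changed
#'   flags (`*_changed`), `cluster`, `subcluster`, `support`.
#' @export
normalize_and_categorize_features <- function(panel, n_flag_clusters = 6) {
  feats <- c("dss", "enhancer", "silencer", "mean_dg_delta")
  invert <- c(dss = FALSE, enhancer = FALSE, silencer = TRUE,
              mean_dg_delta = TRUE)
  out <- panel
  for (f in feats) {
    v <- panel[[f]]
    nz <- v[v != 0]
    if (!length(nz)) {
      out[[paste0(f, "_norm")]] <- rep(0.5, length(v))
      out[[paste0(f, "_changed")]] <- rep(0L, length(v))
      attr(out, "flagged_allzero") <- c(attr(out, "flagged_allzero"), f)
      next
    }
    hi <- quantile(nz, 0.95, type = 7)
    lo <- quantile(nz, 0.05, type = 7)
    w <- v
    w[v != 0 & v > hi] <- hi
    w[v != 0 & v < lo] <- lo
    mx <- max(abs(w))
    if (mx > 0) w <- w / mx
    if (invert[[f]]) w <- -w
    out[[paste0(f, "_norm")]] <- (w + 1) / 2
    out[[paste0(f, "_changed")]] <- as.integer(v != 0)
  }
  flag_mat <- as.matrix(out[, paste0(feats, "_changed")])
  norm_mat <- as.matrix(out[, paste0(feats, "_norm")])
  kflag <- min(n_flag_clusters, nrow(out))
  out$cluster <- if (nrow(out) > 1)
    cutree(hclust(dist(flag_mat), method = "average"), k = kflag)
  else 1L
  out$subcluster <- NA_integer_
  for (cl in unique(out$cluster)) {
    sel <- which(out$cluster == cl)
    if (length(sel) > 2) {
      hh <- hclust(dist(norm_mat[sel, , drop = FALSE]), method = "average")
      out$subcluster[sel] <- cutree(hh, k = min(2, length(sel)))
    } else out$subcluster[sel] <- 1L
  }
  side <- function(x) sign(x - 0.5)  # exact 0.5 = no support
  psi_side <- side(out$psi)
  struct_sup <- side(out$mean_dg_delta_norm) == psi_side & psi_side != 0 &
    side(out$mean_dg_delta_norm) != 0
  sre_cols <- c("dss_norm", "enhancer_norm", "silencer_norm")
  sre_sup <- vapply(seq_len(nrow(out)), function(i)
    any(side(unlist(out[i, sre_cols])) != 0 &
          side(unlist(out[i, sre_cols])) == psi_side[i]), logical(1))
  out$support <- ifelse(struct_sup & sre_sup, "both",
                   ifelse(sre_sup, "SRE",
                     ifelse(struct_sup, "structure", "neither")))
  out
}
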