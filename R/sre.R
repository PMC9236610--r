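#' Build a position weight matrix from a k-mer set
#'
#' Computes a position frequency matrix from a set of equal-width k-mers
#' (over-represented hexamers from splicing-element screens, typically) with
#' a pseudocount, converts to log2 odds against the uniform background 0.25,
#' and attaches the exhaustive 95th-percentile score threshold.
#'
#' @param kmers character vector of equal-width RNA/DNA k-mers.
#' @param name motif name.
#' @param category one of "ESE", "ESS", "ISE", "ISS", "RBP-inclusion",
#'   "RBP-exclusion".
#' @param pseudocount added per base per position before log conversion
#'   (default 0.5).
#' @return a `motif_pwm`: list with `name`, `category`, `width`, `mat`
#'   (4 x width log2-odds matrix, rows A/C/G/U), `threshold`.
#' @export
pwm_from_hexamers <- function(kmers, name = "motif",
                              category = c("ESE", "ESS", "ISE", "ISS",
                                           "RBP-inclusion", "RBP-exclusion"),
                              pseudocount = 0.5) {
  category <- match.arg(category)
  if (!length(kmers)) stop("empty k-mer set")
  kmers <- chartr("T", "U", toupper(kmers))
  w <- unique(nchar(kmers))
  if (length(w) != 1) stop("k-mers of mixed width")
  if (w < 4) stop("k-mer width must be at least 4")
  chars <- do.call(rbind, strsplit(kmers, ""))
  counts <- vapply(seq_len(w), function(p)
    table(factor(chars[, p], levels = c("A", "C", "G", "U"))),
    numeric(4))
  freq <- (counts + pseudocount) / (length(kmers) + 4 * pseudocount)
  pwm_from_pfm(freq, name = name, category = category)
}

#' @rdname pwm_from_hexamers
#' @param pfm 4 x width position frequency matrix (rows A/C/G/U, columns
#'   summing to 1); converted to log2(freq / 0.25).
#' @export
pwm_from_pfm <- function(pfm, name = "motif",
                         category = c("ESE", "ESS", "ISE", "ISS",
                                      "RBP-inclusion", "RBP-exclusion")) {
  category <- match.arg(category)
  stopifnot(is.matrix(pfm), nrow(pfm) == 4)
  rownames(pfm) <- c("A", "C", "G", "U")
  mat <- log2(pfm / 0.25)
  pwm <- structure(list(name = name, category = category,
                        width = ncol(pfm), mat = mat, threshold = NA_real_),
                   class = "motif_pwm")
  pwm$threshold <- pwm_threshold(pwm)
  pwm
}

#' Exhaustive 95th-percentile PWM score threshold
#'
#' Scores all 4^width k-mers and returns the 95th percentile
#' (linear-interpolation quantile).  Only windows whose score exceeds this
#' threshold count as valid motif instances in Delta-strength scans.
#'
#' @param pwm a `motif_pwm`.
#' @param prob percentile (default 0.95).
#' @return numeric threshold.
#' @export
pwm_threshold <- function(pwm, prob = 0.95) {
  w <- pwm$width
  if (w > 10) stop("threshold enumeration limited to width <= 10")
  scores <- 0
  for (p in seq_len(w))
    scores <- as.vector(outer(scores, pwm$mat[, p], "+"))
  unname(quantile(scores, prob, type = 7))
}

#' Score one window under a PWM
#' @param pwm a `motif_pwm`.
#' @param window character string of width `pwm$width`.
#' @return numeric score (sum of per-position log2 odds).
#' @export
score_window <- function(pwm, window) {
  b <- strsplit(chartr("T", "U", toupper(window)), "")[[1]]
  sum(pwm$mat[cbind(match(b, c("A", "C", "G", "U")), seq_along(b))])
}

#' Motif Delta-strengths between wild type and mutant
#'
#' Slides each PWM across its compartment (ESE/ESS over windows fully inside
#' the exon, ISE/ISS fully inside the intron, RBP PWMs over the whole
#' junction; junction-straddling windows are skipped for compartmented
#' categories, and windows truncated by sequence ends are skipped).  Only
#' windows overlapping a mutated position can differ; a window contributes
#' `score(mut) - score(wt)` when `max(score(wt), score(mut))` exceeds the
#' PWM threshold, and contributions are summed into a per-PWM Delta.
#' Per-category aggregates are the mean of non-zero per-PWM Deltas (0 when
#' none); the enhancer aggregate is `ESE + ISE`, the silencer aggregate
#' `ESS + ISS`.
#'
#' @param pwms list of `motif_pwm`.
#' @param wt junction sequence (list with `sequence`, `junction_offset`).
#' @param mutant_seq mutant sequence string, same length as wild type.
#' @return list with `per_pwm` (named numeric), `category` (named numeric
#'   over the categories present), `enhancer`, `silencer`.
#' @export
delta_strength <- function(pwms, wt, mutant_seq) {
  wt_seq <- wt$sequence
  mutant_seq <- normalize_rna(mutant_seq)
  if (nchar(mutant_seq) != nchar(wt_seq))
    stop("wild-type and mutant sequences differ in length")
  mut_pos <- which(strsplit(wt_seq, "")[[1]] != strsplit(mutant_seq, "")[[1]])
  per_pwm <- vapply(pwms, function(pwm)
    pwm_delta_one(pwm, wt_seq, mutant_seq, mut_pos, wt$junction_offset),
    numeric(1))
  names(per_pwm) <- vapply(pwms, `[[`, character(1), "name")
  cats <- vapply(pwms, `[[`, character(1), "category")
  category <- vapply(unique(cats), function(cc) {
    v <- per_pwm[cats == cc]
    nz <- v[v != 0]
    if (length(nz)) mean(nz) else 0
  }, numeric(1))
  get0cat <- function(cc) if (cc %in% names(category)) category[[cc]] else 0
  list(per_pwm = per_pwm, category = category,
       enhancer = get0cat("ESE") + get0cat("ISE"),
       silencer = get0cat("ESS") + get0cat("ISS"))
}

pwm_delta_one <- function(pwm, wt_seq, mutant_seq, mut_pos, junction_offset) {
  if (!length(mut_pos)) return(0)
  n <- nchar(wt_seq)
  w <- pwm$width
  lo <- 1L
  hi <- n - w + 1L
  if (pwm$category %in% c("ESE", "ESS")) hi <- min(hi, junction_offset - w + 1L)
  if (pwm$category %in% c("ISE", "ISS")) lo <- max(lo, junction_offset + 1L)
  if (hi < lo) return(0)
  starts <- lo:hi
  # windows overlapping a mutated position
  keep <- vapply(starts, function(s) any(mut_pos >= s & mut_pos <= s + w - 1),
                 logical(1))
  starts <- starts[keep]
  total <- 0
  for (s in starts) {
    sw <- score_window(pwm, substr(wt_seq, s, s + w - 1))
    sm <- score_window(pwm, substr(mutant_seq, s, s + w - 1))
    if (max(sw, sm) > pwm$threshold) total <- total + (sm - sw)
  }
  total
}

#' Donor splice-site scoring model
#'
#' First-order log2-odds matrix over the 9-mer donor site (last 3 exonic +
#' first 6 intronic nucleotides).  The bundled default is built from the
#' canonical human U1-complementary donor consensus base frequencies
#' (positions -3..+6, near-invariant GU at +1/+2); external score tables can
#' be loaded with [read_splice_site_model()].
#'
#' @param freq optional 4 x 9 frequency matrix (rows A/C/G/U).
#' @return a `splice_site_model`: list with `mat` (4 x 9 log2-odds) and
#'   `exonic` = 3.
#' @export
splice_site_model_default <- function(freq = NULL) {
  if (is.null(freq)) {
    freq <- matrix(c(
      # -3    -2    -1    +1     +2     +3    +4    +5    +6
      0.33, 0.60, 0.08, 0.001, 0.001, 0.59, 0.71, 0.06, 0.17,  # A
      0.37, 0.13, 0.04, 0.001, 0.001, 0.03, 0.08, 0.06, 0.19,  # C
      0.18, 0.14, 0.81, 0.997, 0.001, 0.35, 0.12, 0.82, 0.17,  # G
      0.12, 0.13, 0.07, 0.001, 0.997, 0.03, 0.09, 0.06, 0.47), # U
      nrow = 4, byrow = TRUE,
      dimnames = list(c("A", "C", "G", "U"), NULL))
  }
  stopifnot(nrow(freq) == 4, ncol(freq) == 9)
  structure(list(mat = log2(freq / 0.25), exonic = 3L),
            class = "splice_site_model")
}

#' @rdname splice_site_model_default
#' @param path TSV with 9 columns (positions -3..+6) and 4 rows (A,C,G,U) of
#'   log-odds scores, with row names.
#' @export
read_splice_site_model <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = FALSE,
                            row.names = 1))
  stopifnot(nrow(m) == 4, ncol(m) == 9)
  rownames(m) <- c("A", "C", "G", "U")
  structure(list(mat = m, exonic = 3L), class = "splice_site_model")
}

#' Score a 9-mer donor site
#' @param model a `splice_site_model`.
#' @param ninemer 9-character donor window (3 exonic + 6 intronic).
#' @return numeric score.
#' @export
score_splice_site <- function(model, ninemer) {
  b <- strsplit(chartr("T", "U", toupper(ninemer)), "")[[1]]
  stopifnot(length(b) == 9)
  sum(model$mat[cbind(match(b, c("A", "C", "G", "U")), 1:9)])
}

#' Change in donor splice-site strength
#'
#' Rescoring happens only when a substitution falls within the 9-mer (last 3
#' exonic or first 6 intronic positions); mutations elsewhere leave the
#' donor score unchanged, so Delta SS = 0.  Positive values mean a stronger
#' donor site (favoring inclusion).
#'
#' @param wt junction sequence.
#' @param mutant_seq mutant sequence string.
#' @param model a `splice_site_model`.
#' @return Delta SS (mutant score - wild-type score).
#' @export
splice_site_delta <- function(wt, mutant_seq,
                              model = splice_site_model_default()) {
  off <- wt$junction_offset
  mutant_seq <- normalize_rna(mutant_seq)
  mut_pos <- which(strsplit(wt$sequence, "")[[1]] !=
                     strsplit(mutant_seq, "")[[1]])
  lo <- off - 2L
  hi <- off + 6L
  if (!length(mut_pos) || !any(mut_pos >= lo & mut_pos <= hi)) return(0)
  score_splice_site(model, substr(mutant_seq, lo, hi)) -
    score_splice_site(model, substr(wt$sequence, lo, hi))
}

#' RBP motif Delta-strength aggregates
#'
#' Applies the same window/threshold Delta-strength logic as
#' [delta_strength()] to PWMs of RNA-binding proteins labeled by whether the
#' protein promotes exon exclusion or inclusion, and returns the two
#' mean-of-non-zero aggregates.
#'
#' @param pwms list of `motif_pwm` with categories "RBP-exclusion" /
#'   "RBP-inclusion".
#' @inheritParams delta_strength
#' @return list with `Ex` (exclusion aggregate) and `In` (inclusion
#'   aggregate).
#' @export
rbp_delta <- function(pwms, wt, mutant_seq) {
  ds <- delta_strength(pwms, wt, mutant_seq)
  get0cat <- function(cc) if (cc %in% names(ds$category))
    ds$category[[cc]] else 0
  list(Ex = get0cat("RBP-exclusion"), In = get0cat("RBP-inclusion"),
       per_pwm = ds$per_pwm)
}

#' Read a hexamer set (one k-mer per line) into a PWM
#' @param path plain-text file, one k-mer per line; blank lines and lines
#'   starting with `#` are skipped.
#' @inheritParams pwm_from_hexamers
#' @export
read_hexamer_pwm <- function(path, name = basename(path),
                             category = "ESE", pseudocount = 0.5) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  pwm_from_hexamers(lines, name = name, category = category,
                    pseudocount = pseudocount)
}

#' Bundled synthetic SRE / RBP motif set
#'
#' Loads the small synthetic hexamer sets shipped under `inst/extdata/`
#' (stand-ins for published splicing-element screens, generated for testing
#' and examples; the filenames are marked synthetic).  Two PWMs per SRE
#' category plus one inclusion- and one exclusion-RBP PWM.
#'
#' @return list of `motif_pwm`.
#' @export
synthetic_motif_set <- function() {
  dir <- system.file("extdata", package = "psifold")
  spec <- list(
    c("synthetic_ese_hexamers.txt", "ESE"),
    c("synthetic_ess_hexamers.txt", "ESS"),
    c("synthetic_ise_hexamers.txt", "ISE"),
    c("synthetic_iss_hexamers.txt", "ISS"),
    c("synthetic_rbp_inclusion_hexamers.txt", "RBP-inclusion"),
    c("synthetic_rbp_exclusion_hexamers.txt", "RBP-exclusion"))
  out <- list()
  for (sp in spec) {
    lines <- trimws(readLines(file.path(dir, sp[1])))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    groups <- split(lines, cumsum(startsWith(lines, ">")))
    for (gg in groups) {
      nm <- sub("^>", "", gg[1])
      out[[nm]] <- pwm_from_hexamers(gg[-1], name = nm, category = sp[2])
    }
  }
  out
}
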