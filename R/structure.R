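#' Secondary structure objects
#'
#' A pseudoknot-free pairing of an RNA sequence with CT semantics: a pair
#' table mapping every 1-based position to its partner, 0 when unpaired.
#' Structures must satisfy involution (the partner of my partner is me),
#' contain no crossing pairs, and keep hairpin loops at least 3 nt long.
#'
#' @param sequence RNA string over A/C/G/U (T is accepted and converted).
#' @param pairs integer vector of partner positions (0 = unpaired).
#' @param validate check invariants (default TRUE).
#' @return An object of class `secondary_structure` with fields `sequence`
#'   and `pairs`.
#' @export
secondary_structure <- function(sequence, pairs = NULL, validate = TRUE) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  if (is.null(pairs)) pairs <- integer(n)
  pairs <- as.integer(pairs)
  if (length(pairs) != n)
    stop("pair table length (", length(pairs), ") != sequence length (", n, ")")
  x <- structure(list(sequence = sequence, pairs = pairs),
                 class = "secondary_structure")
  if (validate) validate_structure(x)
  x
}

normalize_rna <- function(sequence) {
  sequence <- toupper(gsub("\\s", "", paste(sequence, collapse = "")))
  sequence <- chartr("T", "U", sequence)
  if (!grepl("^[ACGU]*$", sequence))
    stop("sequence contains characters outside A/C/G/U")
  sequence
}

seq_codes <- function(sequence) {
  match(strsplit(sequence, "")[[1]], c("A", "C", "G", "U")) - 1L
}

validate_structure <- function(x) {
  p <- x$pairs
  n <- length(p)
  if (any(p < 0 | p > n)) stop("pair index out of range")
  idx <- which(p > 0)
  if (any(p[p[idx]] != idx)) stop("pair table is not an involution")
  if (any(p[idx] == idx)) stop("self-pairing")
  # min hairpin: |i - j| > 3
  if (any(abs(p[idx] - idx) <= 3)) stop("hairpin loop shorter than 3 nt")
  # crossing check on (i < j) pairs
  ij <- cbind(idx[p[idx] > idx], p[idx[p[idx] > idx]])
  if (nrow(ij) > 1) {
    o <- order(ij[, 1])
    ij <- ij[o, , drop = FALSE]
    ends <- integer(0)
    for (r in seq_len(nrow(ij))) {
      ends <- ends[ends >= ij[r, 1]]
      if (length(ends) && any(ends < ij[r, 2] & ij[r, 1] < ends &
                              ij[r, 2] > ends))
        stop("crossing pairs (pseudoknot)")
      ends <- c(ends, ij[r, 2])
    }
  }
  invisible(x)
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("secondary_structure:", nchar(x$sequence), "nt,",
      sum(x$pairs > 0) / 2, "pairs\n")
  cat(x$sequence, "\n")
  cat(format_dotbracket(x), "\n")
  invisible(x)
}

#' Pairs of a structure as a two-column matrix (i < j)
#' @param x a `secondary_structure`.
#' @return integer matrix with columns i, j.
#' @export
pair_list <- function(x) {
  i <- which(x$pairs > seq_along(x$pairs))
  cbind(i = i, j = x$pairs[i])
}

#' Parse / format dot-bracket notation
#'
#' @param db dot-bracket string (matched round brackets, dots unpaired).
#' @param sequence the RNA sequence of equal length.
#' @return `parse_dotbracket`: a `secondary_structure`;
#'   `format_dotbracket`: a string.
#' @export
parse_dotbracket <- function(db, sequence) {
  ch <- strsplit(db, "")[[1]]
  n <- length(ch)
  pairs <- integer(n)
  stk <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") stk <- c(stk, i)
    else if (ch[i] == ")") {
      if (!length(stk)) stop("unbalanced brackets")
      j <- stk[length(stk)]
      stk <- stk[-length(stk)]
      pairs[i] <- j
      pairs[j] <- i
    } else if (ch[i] != ".") stop("unexpected character '", ch[i], "'")
  }
  if (length(stk)) stop("unbalanced brackets")
  secondary_structure(sequence, pairs)
}

#' @rdname parse_dotbracket
#' @param x a `secondary_structure`.
#' @export
format_dotbracket <- function(x) {
  p <- x$pairs
  out <- rep(".", length(p))
  out[p > seq_along(p)] <- "("
  out[p > 0 & p < seq_along(p)] <- ")"
  paste(out, collapse = "")
}

#' Read / write CT files
#'
#' Connect-table format: a header line with the nucleotide count (plus an
#' optional title), then six columns per nucleotide: index, base, index-1,
#' index+1, partner (0 = unpaired), index.
#'
#' @param path file path.
#' @return `read_ct`: a list of `secondary_structure` (CT files may hold
#'   several structures); `write_ct` invisibly returns `path`.
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]][1])
    body <- lines[(i + 1):(i + n)]
    f <- do.call(rbind, strsplit(trimws(body), "\\s+"))
    sequence <- paste(f[, 2], collapse = "")
    pairs <- as.integer(f[, 5])
    out[[length(out) + 1]] <- secondary_structure(sequence, pairs)
    i <- i + n + 1
  }
  out
}

#' @rdname read_ct
#' @param structures a `secondary_structure` or list of them.
#' @param title optional per-structure title.
#' @export
write_ct <- function(structures, path, title = "psifold") {
  if (inherits(structures, "secondary_structure"))
    structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in structures) {
    n <- nchar(s$sequence)
    b <- strsplit(s$sequence, "")[[1]]
    writeLines(sprintf("%d %s", n, title), con)
    writeLines(sprintf("%d %s %d %d %d %d", seq_len(n), b,
                       seq_len(n) - 1L, c(seq_len(n - 1) + 1L, 0L),
                       s$pairs, seq_len(n)), con)
  }
  invisible(path)
}

#' Element-string annotation of a structure
#'
#' Classifies every nucleotide by the structural element holding it:
#' stem `s`, hairpin loop `h`, other loops (interior, bulge, multibranch,
#' exterior segments between helices) `m`, and unpaired 5'/3' tails `f`/`t`.
#' On a fully open chain, positions before the midpoint are `f`, after `t`.
#'
#' @param x a `secondary_structure`.
#' @param digitize return integer codes (f,t = 0, s = 1, h = 2, m = 3)
#'   instead of letters.
#' @return character (or integer) vector, one entry per nucleotide.
#' @export
element_string <- function(x, digitize = FALSE) {
  p <- x$pairs
  n <- length(p)
  out <- character(n)
  out[p > 0] <- "s"
  un <- which(p == 0)
  if (length(un)) {
    paired <- which(p > 0)
    if (!length(paired)) {
      out[un] <- ifelse(un <= n / 2, "f", "t")
    } else {
      first <- min(paired); last <- max(paired)
      for (i in un) {
        if (i < first) { out[i] <- "f"; next }
        if (i > last)  { out[i] <- "t"; next }
        # innermost pair enclosing i decides: hairpin if its loop has no pairs
        encl <- enclosing_pair(p, i)
        if (is.null(encl)) { out[i] <- "m"; next }  # exterior between helices
        inner <- (encl[1] + 1):(encl[2] - 1)
        out[i] <- if (all(p[inner] == 0)) "h" else "m"
      }
    }
  }
  if (digitize) {
    unname(c(f = 0L, t = 0L, s = 1L, h = 2L, m = 3L)[out])
  } else out
}

# innermost pair (i,j) strictly enclosing position k, or NULL
enclosing_pair <- function(p, k) {
  best <- NULL
  i <- k - 1
  while (i >= 1) {
    if (p[i] > k) { best <- c(i, p[i]); break }
    if (p[i] > 0 && p[i] < i) { i <- p[i] - 1; next }  # skip closed helix
    i <- i - 1
  }
  best
}
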