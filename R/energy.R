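#' Nearest-neighbor energy model
#'
#' A self-contained, documented parameter set for pseudoknot-free secondary
#' structure thermodynamics: a 6 x 6 stacking table over the pair alphabet
#' (AU, UA, CG, GC, GU, UG), logarithmic hairpin and interior/bulge loop
#' penalties, an affine multibranch-loop penalty, and a terminal penalty for
#' helix-end AU/GU pairs.  All energies are in kcal/mol at the given
#' temperature.  The default stacking table is generated from per-pair
#' strengths h(CG) = 3.3, h(AU) = 1.1, h(GU) = 0.7 as
#' stack(p, q) = -(h(p) + h(q))/2 - 0.4, which reproduces the qualitative
#' ordering of nearest-neighbor stacks (GC-rich strongest, wobble weakest).
#' The table is plain data: measured parameters can be dropped in with
#' [read_energy_model()].
#'
#' @param stack 6 x 6 numeric matrix, rows/cols named AU, UA, CG, GC, GU, UG;
#'   `stack[p, q]` is the energy of pair q stacked directly inside pair p.
#' @param hairpin_base,loop_coef hairpin penalty
#'   `hairpin_base + loop_coef * log(l/3)` for loop length l >= 3.
#' @param internal_base,internal_coef interior/bulge penalty
#'   `internal_base + internal_coef * log(s)` for s >= 1 unpaired nucleotides.
#' @param ml_init,ml_branch,ml_unpaired affine multibranch penalty
#'   `ml_init + ml_branch * (branches + 1) + ml_unpaired * unpaired`
#'   (the closing pair counts as a branch).
#' @param terminal_pen penalty per AU/UA/GU/UG closing or branch pair.
#' @param temperature kelvin; RT = 0.0019872 * temperature.
#' @param maxloop interior-loop size cap used by the dynamic programs (the
#'   energy evaluator itself scores any size).
#' @return list of class `energy_model`.
#' @export
energy_model <- function(stack = default_stack(),
                         hairpin_base = 5.0, loop_coef = 1.08,
                         internal_base = 3.5, internal_coef = 1.08,
                         ml_init = 3.4, ml_branch = 0.4, ml_unpaired = 0.1,
                         terminal_pen = 0.5,
                         temperature = 310.15, maxloop = 30L) {
  stopifnot(is.matrix(stack), all(dim(stack) == c(6, 6)))
  dimnames(stack) <- list(PAIR_ALPHABET, PAIR_ALPHABET)
  structure(list(stack = stack,
                 hairpin_base = hairpin_base, loop_coef = loop_coef,
                 internal_base = internal_base, internal_coef = internal_coef,
                 ml_init = ml_init, ml_branch = ml_branch,
                 ml_unpaired = ml_unpaired, terminal_pen = terminal_pen,
                 temperature = temperature,
                 RT = 0.0019872 * temperature,
                 maxloop = as.integer(maxloop)),
            class = "energy_model")
}

PAIR_ALPHABET <- c("AU", "UA", "CG", "GC", "GU", "UG")

default_stack <- function() {
  h <- c(AU = 1.1, UA = 1.1, CG = 3.3, GC = 3.3, GU = 0.7, UG = 0.7)
  m <- -outer(h, h, function(a, b) (a + b) / 2) - 0.4
  dimnames(m) <- list(PAIR_ALPHABET, PAIR_ALPHABET)
  m
}

#' Read / write an energy model as a versioned TSV
#'
#' Scalar parameters as `param<TAB>value` lines, then the stacking table as
#' `stack<TAB>outer<TAB>inner<TAB>value` lines.
#'
#' @param path file path.
#' @return `read_energy_model`: an `energy_model`.
#' @export
read_energy_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  is_stack <- vapply(f, function(x) x[1] == "stack", logical(1))
  sc <- f[!is_stack]
  pars <- setNames(vapply(sc, function(x) as.numeric(x[2]), numeric(1)),
                   vapply(sc, `[`, character(1), 1))
  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_ALPHABET, PAIR_ALPHABET))
  for (x in f[is_stack]) stack[x[2], x[3]] <- as.numeric(x[4])
  if (anyNA(stack)) stop("incomplete stacking table in ", path)
  energy_model(stack = stack,
               hairpin_base = pars[["hairpin_base"]],
               loop_coef = pars[["loop_coef"]],
               internal_base = pars[["internal_base"]],
               internal_coef = pars[["internal_coef"]],
               ml_init = pars[["ml_init"]], ml_branch = pars[["ml_branch"]],
               ml_unpaired = pars[["ml_unpaired"]],
               terminal_pen = pars[["terminal_pen"]],
               temperature = pars[["temperature"]],
               maxloop = pars[["maxloop"]])
}

#' @rdname read_energy_model
#' @param model an `energy_model`.
#' @export
write_energy_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# psifold energy model v1", con)
  for (p in c("hairpin_base", "loop_coef", "internal_base", "internal_coef",
              "ml_init", "ml_branch", "ml_unpaired", "terminal_pen",
              "temperature", "maxloop"))
    writeLines(paste(p, model[[p]], sep = "\t"), con)
  for (a in PAIR_ALPHABET) for (b in PAIR_ALPHABET)
    writeLines(paste("stack", a, b, model$stack[a, b], sep = "\t"), con)
  invisible(path)
}

#' Evaluate the free energy of a structure
#'
#' Sums stacking energies and loop penalties over the loop decomposition of
#' the structure; when a pseudo-energy model and a reactivity profile are
#' given, per-nucleotide reactivity pseudo-energies are added for every
#' paired nucleotide.  An open chain without pseudo terms scores 0.
#'
#' @param x a `secondary_structure`.
#' @param model an [energy_model()].
#' @param pseudo optional [pseudo_energy_model()].
#' @param profile optional reactivity profile (required with `pseudo`).
#' @return free energy change in kcal/mol.
#' @export
evaluate_energy <- function(x, model = energy_model(), pseudo = NULL,
                            profile = NULL) {
  validate_structure(x)
  g <- pseudo_energy_vector(pseudo, profile, nchar(x$sequence), model)
  cpp_energy(seq_codes(x$sequence), x$pairs, unclass(model), g)
}

# per-position pseudo-energy vector (0 without a pseudo model)
pseudo_energy_vector <- function(pseudo, profile, n, model) {
  if (is.null(pseudo)) return(numeric(n))
  if (is.null(profile)) stop("pseudo-energy model given without a profile")
  pseudo_energies(pseudo, profile, n, model)
}
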