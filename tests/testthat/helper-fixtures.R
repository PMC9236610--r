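# shared fixtures and independent reference implementations for oracles

# toy energy model with round numbers for hand computation:
# every stack -2.0, hairpin penalty flat 5.0, internal flat 3.0,
# multibranch 3 + 0.4/branch + 0.1/unpaired, AU/GU terminal 0.5
toy_model <- function() {
  st <- matrix(-2, 6, 6)
  energy_model(stack = st, hairpin_base = 5, loop_coef = 0,
               internal_base = 3, internal_coef = 0,
               ml_init = 3, ml_branch = 0.4, ml_unpaired = 0.1,
               terminal_pen = 0.5)
}

# independent R reference scorer (loop decomposition written separately
# from the compiled evaluator)
ref_energy <- function(x, model) {
  p <- x$pairs
  n <- length(p)
  codes <- strsplit(x$sequence, "")[[1]]
  ptype <- function(i, j) paste0(codes[i], codes[j])
  pen <- function(i, j) {
    if (ptype(i, j) %in% c("CG", "GC")) 0 else model$terminal_pen
  }
  E <- 0
  # branches at the top level of interval (a, b), exclusive bounds
  toplevel <- function(a, b) {
    out <- NULL
    k <- a
    while (k <= b) {
      if (p[k] > k) { out <- rbind(out, c(k, p[k])); k <- p[k] + 1 }
      else k <- k + 1
    }
    out
  }
  for (i in which(p > seq_len(n))) {
    j <- p[i]
    br <- toplevel(i + 1, j - 1)
    nb <- if (is.null(br)) 0 else nrow(br)
    if (nb == 0) {
      E <- E + model$hairpin_base + model$loop_coef * log((j - i - 1) / 3) +
        pen(i, j)
    } else if (nb == 1 && br[1, 1] == i + 1 && br[1, 2] == j - 1) {
      E <- E + model$stack[ptype(i, j), ptype(i + 1, j - 1)]
    } else if (nb == 1) {
      s <- (br[1, 1] - i - 1) + (j - br[1, 2] - 1)
      E <- E + model$internal_base + model$internal_coef * log(s) +
        pen(i, j) + pen(br[1, 1], br[1, 2])
    } else {
      u <- (j - i - 1) - sum(br[, 2] - br[, 1] + 1)
      E <- E + model$ml_init + model$ml_branch * (nb + 1) +
        model$ml_unpaired * u + pen(i, j) +
        sum(apply(br, 1, function(r) pen(r[1], r[2])))
    }
  }
  ext <- toplevel(1, n)
  if (!is.null(ext))
    E <- E + sum(apply(ext, 1, function(r) pen(r[1], r[2])))
  E
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")

# small planted-hairpin fixture shared across tests
fixture_junction <- function(len = 60, off = 25, arm = 7, seed = 101) {
  gen_junction_sequence(len, off, arm, seed = seed)
}

fixture_profile <- function(js, seed = 202) {
  prepare_for_folding(
    simulate_reactivities(js$true_structure,
                          reactivity_sim_params(seed = seed)))
}

fixture_pseudo <- function() pseudo_energy_model(context_distributions_gamma())
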