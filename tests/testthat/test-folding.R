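test_that("unpairable sequences have Z = 1, no pairs, open-chain MFE", {
  m <- energy_model()
  pf <- partition_function("AAAAAAAAAA", m)
  expect_equal(pf$logZ, 0)
  expect_true(all(pf$pair_prob == 0))
  mfe <- mfe_fold("AAAAAAAAAA", m)
  expect_true(all(mfe$pairs == 0))
  expect_equal(attr(mfe, "energy"), 0)
  ens <- sample_structures("AAAAAAAAAA", m, n = 25, seed = 4)
  expect_true(all(ens$pairs == 0))
})

test_that("enumeration count matches an independent pairing recursion", {
  # independent count: number of non-crossing canonical pair sets with
  # min hairpin 3, by interval recursion on counts only
  count_structs <- function(s) {
    b <- strsplit(s, "")[[1]]
    ok <- function(x, y) paste0(x, y) %in%
      c("AU", "UA", "CG", "GC", "GU", "UG")
    n <- nchar(s)
    memo <- matrix(NA_real_, n + 1, n + 1)
    cnt <- function(i, j) {
      if (i >= j) return(1)
      if (!is.na(memo[i, j])) return(memo[i, j])
      total <- cnt(i + 1, j)
      for (k in if (j >= i + 4) (i + 4):j else integer(0)) {
        if (ok(b[i], b[k]))
          total <- total + cnt(i + 1, k - 1) * cnt(k + 1, j)
      }
      memo[i, j] <<- total
      total
    }
    cnt(1, n)
  }
  for (s in c("GGGAAACCC", "GGCGAAAGCUAAGC", "ACGUACGUACGU")) {
    en <- enumerate_structures(s)
    expect_equal(length(en$structures), count_structs(s))
    for (x in en$structures) expect_silent(validate_structure(x))
  }
  expect_equal(length(enumerate_structures("AAAA")$structures), 1)
  expect_error(enumerate_structures(random_rna(25)), "refused")
})

test_that("partition function, pair probabilities and MFE match exhaustive
           enumeration on random short sequences", {
  m <- energy_model()
  set.seed(99)
  n_cases <- 200
  for (case in seq_len(n_cases)) {
    s <- random_rna(sample(6:14, 1))
    en <- enumerate_structures(s, m)
    w <- exp(-en$energies / m$RT)
    Z <- sum(w)
    pf <- partition_function(s, m)
    expect_equal(pf$logZ, log(Z), tolerance = 1e-9)
    P <- matrix(0, nchar(s), nchar(s))
    for (k in seq_along(en$structures)) {
      pl <- pair_list(en$structures[[k]])
      if (nrow(pl))
        P[pl] <- P[pl] + w[k]
    }
    expect_equal(pf$pair_prob, P / Z, tolerance = 1e-9)
    expect_equal(attr(mfe_fold(s, m), "energy"), min(en$energies),
                 tolerance = 1e-9)
  }
})

test_that("reactivity pseudo-energies keep the engine consistent with the
           enumeration oracle", {
  m <- energy_model()
  ps <- fixture_pseudo()
  set.seed(17)
  for (case in 1:20) {
    js <- gen_junction_sequence(13, 6, 3, seed = case)
    prof <- fixture_profile(js, seed = case + 50)
    en <- enumerate_structures(js$sequence, m, pseudo = ps, profile = prof)
    Z <- sum(exp(-en$energies / m$RT))
    pf <- partition_function(js$sequence, m, ps, prof)
    expect_equal(pf$logZ, log(Z), tolerance = 1e-9)
    expect_equal(attr(mfe_fold(js$sequence, m, ps, prof), "energy"),
                 min(en$energies), tolerance = 1e-9)
  }
})

test_that("an all-sentinel profile reproduces the no-pseudo computation
           exactly", {
  m <- energy_model()
  ps <- fixture_pseudo()
  js <- fixture_junction()
  prof <- fixture_profile(js)
  prof$reactivity <- -999
  base <- partition_function(js$sequence, m)
  masked <- partition_function(js$sequence, m, ps, prof)
  expect_identical(base$logZ, masked$logZ)
  expect_identical(base$pair_prob, masked$pair_prob)
})

test_that("raising one nucleotide's reactivity lowers its paired
           probability", {
  m <- energy_model()
  ps <- fixture_pseudo()
  js <- fixture_junction(len = 40, off = 18, arm = 5)
  prof <- fixture_profile(js)
  # an A/C position paired in the planted hairpin
  cand <- which(js$true_structure$pairs > 0 &
                  prof$base %in% c("A", "C"))[1]
  expect_false(is.na(cand))
  probs <- vapply(c(0.05, 0.5, 1.5, 3), function(r) {
    p2 <- prof
    p2$reactivity[cand] <- r
    partition_function(js$sequence, m, ps, p2)$paired_prob[cand]
  }, numeric(1))
  expect_true(all(diff(probs) < 0))
})

test_that("sampled frequencies match Boltzmann probabilities on a toy with
           few structures", {
  m <- energy_model()
  s <- "GGAAAACCAA"  # handful of legal structures
  en <- enumerate_structures(s, m)
  prob <- exp(-en$energies / m$RT)
  prob <- prob / sum(prob)
  keys <- vapply(en$structures, format_dotbracket, character(1))
  n <- 10000
  ens <- sample_structures(s, m, n = n, seed = 8)
  got <- vapply(seq_len(n), function(r)
    format_dotbracket(ensemble_member(ens, r)), character(1))
  emp <- table(factor(got, levels = keys)) / n
  tol <- 4 * sqrt(prob * (1 - prob) / n)
  expect_true(all(abs(as.numeric(emp) - prob) <= pmax(tol, 1e-4)))
})

test_that("sampling is seed-deterministic and seed-sensitive", {
  m <- energy_model()
  js <- fixture_junction()
  a <- sample_structures(js$sequence, m, n = 40, seed = 5)
  b <- sample_structures(js$sequence, m, n = 40, seed = 5)
  c <- sample_structures(js$sequence, m, n = 40, seed = 6)
  expect_identical(a$pairs, b$pairs)
  expect_false(identical(a$pairs, c$pairs))
})

test_that("ensemble pairing frequencies match the DP pair-probability
           matrix", {
  m <- energy_model()
  js <- fixture_junction(len = 30, off = 14, arm = 5)
  pf <- partition_function(js$sequence, m)
  n <- 10000
  ens <- sample_structures(js$sequence, m, n = n, seed = 12)
  len <- nchar(js$sequence)
  emp <- matrix(0, len, len)
  for (r in seq_len(n)) {
    p <- ens$pairs[r, ]
    i <- which(p > seq_along(p))
    emp[cbind(i, p[i])] <- emp[cbind(i, p[i])] + 1
  }
  emp <- emp / n
  se <- sqrt(pf$pair_prob * (1 - pf$pair_prob) / n)
  expect_true(all(abs(emp - pf$pair_prob) <= 4 * pmax(se, 2e-4)))
})

test_that("MFE on the planted-hairpin fixture contains the planted helix", {
  m <- energy_model()
  ps <- fixture_pseudo()
  js <- fixture_junction()
  prof <- fixture_profile(js)
  mfe <- mfe_fold(js$sequence, m, ps, prof)
  planted <- pair_list(js$true_structure)
  found <- sum(mfe$pairs[planted[, 1]] == planted[, 2])
  expect_gte(found / nrow(planted), 0.8)
})
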