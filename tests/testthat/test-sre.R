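test_that("PWM construction follows the log2 frequency-over-background
           rule", {
  # a PFM entry of 0.5 converts to weight log2(0.5 / 0.25) = 1
  pfm <- matrix(c(0.5, 0.25, 0.125, 0.125), 4, 6)
  pwm <- pwm_from_pfm(pfm, category = "ESE")
  expect_equal(unname(pwm$mat["A", 1]), 1)
  expect_equal(unname(pwm$mat["C", 1]), 0)
  # uniform PFM: all-zero PWM, threshold 0
  uni <- pwm_from_pfm(matrix(0.25, 4, 6), category = "ESE")
  expect_true(all(uni$mat == 0))
  expect_equal(uni$threshold, 0)
  # a single hexamer maximizes the weight of its own bases
  g6 <- pwm_from_hexamers("GGGGGG", category = "ISE")
  expect_true(all(apply(g6$mat, 2, which.max) == 3))
  expect_error(pwm_from_hexamers(c("AAAAAA", "CCCCC"), category = "ESE"),
               "mixed")
})

test_that("thresholds equal brute-force 95th percentiles over all 4096
           hexamers and scale linearly", {
  pwms <- synthetic_motif_set()
  kmer_scores <- function(pwm) {
    b <- c("A", "C", "G", "U")
    grid <- expand.grid(rep(list(b), pwm$width), stringsAsFactors = FALSE)
    apply(grid, 1, function(km) score_window(pwm, paste(km, collapse = "")))
  }
  for (pwm in pwms) {
    brute <- unname(quantile(kmer_scores(pwm), 0.95, type = 7))
    expect_equal(pwm$threshold, brute, tolerance = 1e-12)
    scaled <- pwm
    scaled$mat <- 3 * pwm$mat
    expect_equal(pwm_threshold(scaled), 3 * pwm$threshold,
                 tolerance = 1e-12)
  }
})

toy_junction <- function(seq, off) list(sequence = seq,
                                        junction_offset = as.integer(off))

test_that("Delta strength is zero for identical sequences and gated by the
           threshold", {
  pwms <- synthetic_motif_set()
  js <- fixture_junction()
  ds <- delta_strength(pwms, js, js$sequence)
  expect_true(all(ds$per_pwm == 0))
  expect_equal(ds$enhancer, 0)
  expect_equal(ds$silencer, 0)
  # a mutation whose windows all stay below threshold contributes nothing
  pwm <- pwm_from_hexamers(c("GGGGGG", "GGGGGU"), name = "g6",
                           category = "ESE")
  js2 <- toy_junction("AAAAAAAAAACCCC", 10)
  mut <- "AAAAACAAAACCCC"  # A>C in an A-context: scores far below threshold
  ds2 <- delta_strength(list(pwm), js2, mut)
  expect_equal(unname(ds2$per_pwm), 0)
})

test_that("a single above-threshold window reproduces the hand-computed
           difference, verified against a full-scan oracle", {
  pwm <- pwm_from_hexamers(c("GAAGAA", "GAAGAG", "GAAGGA"), name = "ese",
                           category = "ESE")
  wt_seq <- "CCCCGAAGAACCCCCAAAAA"
  js <- toy_junction(wt_seq, 15)
  mut <- sub("GAAGAA", "GAAGCA", wt_seq)
  ds <- delta_strength(list(pwm), js, mut)
  # oracle: scan every exonic window of both alleles
  oracle <- 0
  for (s in 1:(15 - 6 + 1)) {
    sw <- score_window(pwm, substr(wt_seq, s, s + 5))
    sm <- score_window(pwm, substr(mut, s, s + 5))
    if (sw != sm && max(sw, sm) > pwm$threshold)
      oracle <- oracle + (sm - sw)
  }
  expect_equal(unname(ds$per_pwm), oracle)
  expect_false(oracle == 0)
})

test_that("Delta strength is local and antisymmetric", {
  pwms <- synthetic_motif_set()
  js <- fixture_junction()
  chars <- strsplit(js$sequence, "")[[1]]
  p <- 12
  mut_chars <- chars
  mut_chars[p] <- setdiff(c("A", "C", "G", "U"), chars[p])[1]
  mut <- paste(mut_chars, collapse = "")
  # locality: windows not covering p are identical between alleles by
  # construction; full-scan comparison over every pwm and window
  for (pwm in pwms) {
    w <- pwm$width
    for (s in seq_len(nchar(mut) - w + 1)) {
      if (p >= s && p <= s + w - 1) next
      expect_identical(score_window(pwm, substr(js$sequence, s, s + w - 1)),
                       score_window(pwm, substr(mut, s, s + w - 1)))
    }
  }
  # symmetry: swapping the roles of wt and mutant negates every Delta
  fwd <- delta_strength(pwms, js, mut)
  js_mut <- list(sequence = mut, junction_offset = js$junction_offset)
  rev <- delta_strength(pwms, js_mut, js$sequence)
  expect_equal(rev$per_pwm, -fwd$per_pwm)
})

test_that("compartment restriction keeps exonic PWMs out of the intron", {
  pwm_e <- pwm_from_hexamers(c("GAAGAA", "GAAGAG"), name = "e",
                             category = "ESE")
  pwm_i <- pwm_from_hexamers(c("GAAGAA", "GAAGAG"), name = "i",
                             category = "ISE")
  # motif-disrupting mutation deep in the intron
  wt_seq <- "AAAAAAAAAAAAGAAGAAAA"
  js <- toy_junction(wt_seq, 8)
  mut <- "AAAAAAAAAAAAGACGAAAA"
  expect_equal(unname(delta_strength(list(pwm_e), js, mut)$per_pwm), 0)
  expect_false(delta_strength(list(pwm_i), js, mut)$per_pwm == 0)
})

test_that("donor-site Delta responds only to mutations inside the 9-mer", {
  js <- fixture_junction()
  off <- js$junction_offset
  chars <- strsplit(js$sequence, "")[[1]]
  model <- splice_site_model_default()
  # +19 intronic mutation: outside the first six intronic bases
  p_out <- off + 19
  mm <- chars; mm[p_out] <- setdiff(c("A","C","G","U"), chars[p_out])[1]
  expect_equal(splice_site_delta(js, paste(mm, collapse = ""), model), 0)
  expect_equal(splice_site_delta(js, js$sequence, model), 0)
  # +5 mutation: direct matrix lookup
  p_in <- off + 5
  alt <- setdiff(c("A", "C", "G", "U"), chars[p_in])[1]
  mm2 <- chars; mm2[p_in] <- alt
  d <- splice_site_delta(js, paste(mm2, collapse = ""), model)
  expect_equal(d, unname(model$mat[alt, 8] - model$mat[chars[p_in], 8]))
})

test_that("a toy +5 G gain scores the matrix difference directly", {
  mat <- matrix(0, 4, 9, dimnames = list(c("A", "C", "G", "U"), NULL))
  mat["G", 8] <- 1  # +5 position is matrix column 8
  mat["A", 8] <- -0.3
  model <- structure(list(mat = mat, exonic = 3L),
                     class = "splice_site_model")
  js <- toy_junction("CCCCCCCCCCAAAAAAAAAA", 10)
  mut <- "CCCCCCCCCCAAAAGAAAAA"  # A>G at +5
  expect_equal(splice_site_delta(js, mut, model), 1 - (-0.3))
})

test_that("RBP aggregates split by inclusion/exclusion and match a brute
           scan", {
  inc <- pwm_from_hexamers(c("GAAGGA", "GAAGGU"), name = "in",
                           category = "RBP-inclusion")
  exc <- pwm_from_hexamers(c("UUUGUU", "UUUUUU"), name = "ex",
                           category = "RBP-exclusion")
  wt_seq <- "CCCGAAGGACCCCCAAAAACCCCAAAAAAA"
  js <- toy_junction(wt_seq, 14)
  # disrupt only the inclusion motif
  mut <- sub("GAAGGA", "GACGGA", wt_seq)
  res <- rbp_delta(list(inc, exc), js, mut)
  expect_equal(res$Ex, 0)
  expect_equal(res$In, unname(res$per_pwm["in"]))
  expect_false(res$In == 0)
  # no motif near the mutation: both aggregates zero
  far <- paste0(substr(wt_seq, 1, 29), "U")
  res2 <- rbp_delta(list(inc, exc), js, far)
  expect_equal(c(res2$Ex, res2$In), c(0, 0))
})
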