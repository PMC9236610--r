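test_that("unfolding a region removes exactly the pairs touching it", {
  js <- fixture_junction()
  m <- energy_model()
  mfe <- mfe_fold(js$sequence, m)
  for (interval in list(c(1, 5), c(20, 30), c(10, 45))) {
    out <- unfold_region(mfe, interval)
    # brute-force set filter
    keep <- pair_list(mfe)
    touches <- keep[, 1] >= interval[1] & keep[, 1] <= interval[2] |
      keep[, 2] >= interval[1] & keep[, 2] <= interval[2]
    expect_equal(pair_list(out), keep[!touches, , drop = FALSE])
    expect_silent(validate_structure(out))
  }
  # region covering no paired position: identity
  open_cols <- which(mfe$pairs == 0)
  if (length(open_cols)) {
    iv <- c(open_cols[1], open_cols[1])
    expect_identical(unfold_region(mfe, iv)$pairs, mfe$pairs)
  }
})

test_that("region growth only grows the removed-pair set", {
  js <- fixture_junction()
  mfe <- mfe_fold(js$sequence, energy_model())
  removed <- function(iv) {
    pl <- pair_list(mfe)
    pl[pl[, 1] >= iv[1] & pl[, 1] <= iv[2] |
         pl[, 2] >= iv[1] & pl[, 2] <= iv[2], , drop = FALSE]
  }
  a <- removed(c(22, 28))
  b <- removed(c(18, 35))
  expect_true(all(paste(a[, 1], a[, 2]) %in% paste(b[, 1], b[, 2])))
  expect_lte(sum(unfold_region(mfe, c(18, 35))$pairs > 0),
             sum(unfold_region(mfe, c(22, 28))$pairs > 0))
})

test_that("unfolding energies match hand computation on a toy hairpin", {
  m <- toy_model()
  x <- parse_dotbracket("((((....))))", "AGGCAAAAGCCU")
  e_folded <- evaluate_energy(x, m)  # -0.5 under toy parameters
  # entire hairpin inside the region: unfolded form is the open chain (0)
  expect_equal(delta_g_unfold(x, c(1, 12), m), -e_folded)
  expect_equal(delta_g_unfold(x, c(1, 12), m), 0.5)
  # region with no paired nucleotide costs nothing
  expect_equal(delta_g_unfold(x, c(5, 8), m), 0)
})

test_that("ensemble unfolding statistics reduce to the stored value list", {
  js <- fixture_junction()
  m <- energy_model()
  ps <- fixture_pseudo()
  prof <- fixture_profile(js)
  ens <- sample_structures(js$sequence, m, ps, prof, n = 150, seed = 9)
  region <- footprint_region("splice_site", js)
  st <- ensemble_unfolding_stats(ens, region, m, ps, prof, js = js)
  v <- st$values
  expect_equal(st$n, 150)
  expect_equal(st$mean, mean(v))
  expect_equal(st$sd, sqrt(mean((v - mean(v))^2)))
  if (st$sd > 0) {
    expect_equal(st$skew, mean((v - mean(v))^3) / st$sd^3)
    expect_equal(st$kurtosis, mean((v - mean(v))^4) / st$sd^4 - 3)
  }
  # direct recomputation per member
  direct <- vapply(seq_len(ens$n), function(r)
    delta_g_unfold(ensemble_member(ens, r), attr(region, "interval"),
                   m, ps, prof), numeric(1))
  expect_equal(v, direct)
  # nonnegative disruption cost across the ensemble
  expect_true(all(v >= 0))
})

test_that("degenerate ensembles give zero spread and defined moments", {
  js <- fixture_junction()
  ens <- sample_structures(js$sequence, energy_model(), n = 5, seed = 2)
  ens$pairs <- ens$pairs[rep(1, 5), ]  # identical members
  st <- ensemble_unfolding_stats(ens, c(20, 30))
  expect_equal(st$sd, 0)
  expect_equal(st$skew, 0)
  expect_equal(st$kurtosis, 0)
  # two-member toy {2, 4}: population moments
  expect_equal(mean(c(2, 4)), 3)
  v <- c(2, 4)
  expect_equal(sqrt(mean((v - mean(v))^2)), 1)
})

test_that("footprint table and region widths match the stage definitions", {
  tab <- footprint_table()
  widths <- setNames(tab$exonic + tab$intronic, tab$stage)
  expect_equal(widths, c(PreB = 10L, B = 27L, PreBact = 29L, Bact = 43L))
  js <- gen_junction_sequence(234, 93, 10, seed = 7)
  iv <- attr(footprint_region("Bact", js), "interval")
  expect_equal(unname(iv), c(82L, 124L))
  expect_equal(unname(diff(iv)) + 1L, 43L)
  ss <- attr(footprint_region("splice_site", js), "interval")
  expect_equal(unname(diff(ss)) + 1L, 9L)
  expect_error(footprint_region("Bmax"), "unknown")
  expect_error(resolve_region(junction_region(200, 10), js), "bounds")
})

test_that("footprint counting from synthetic coordinates recovers the
           deposited stage counts", {
  for (counts in list(c(12, 31), c(10, 17), c(2, 8), c(0, 0))) {
    fx <- make_synthetic_coordinates(counts[1], counts[2])
    if (sum(counts) == 0) {
      got <- count_footprint_from_coordinates(fx$path, fx$chain_id,
                                              fx$junction_residue)
      expect_equal(unname(got), c(0, 0))
    } else {
      got <- count_footprint_from_coordinates(fx$path, fx$chain_id,
                                              fx$junction_residue)
      expect_equal(unname(got), counts)
    }
    unlink(fx$path)
  }
  fx <- make_synthetic_coordinates(3, 4)
  expect_error(count_footprint_from_coordinates(fx$path, "Z", 3), "chain")
})

test_that("exon-independence scan stays at 1 for a self-contained exon
           hairpin with unpairable extensions", {
  # exon carries a strong hairpin; extension is poly-A (cannot pair)
  exon <- gen_junction_sequence(30, 15, 6, seed = 41)
  seq_full <- paste0(exon$sequence, strrep("A", 10))
  js <- list(sequence = seq_full, junction_offset = 30L)
  scan <- exon_independence_scan(js, c(1, 30), model = energy_model())
  expect_equal(nrow(scan), 11)
  expect_true(all(scan$fraction_intra == 1))
})

test_that("a complementary extension eventually captures exonic pairs", {
  # A/C-only exon cannot pair with itself; the extension is its complement
  exon_seq <- "AAAAACCCCC"
  ext <- "GGGGGUUUUU"
  js <- list(sequence = paste0(exon_seq, ext), junction_offset = 10L)
  scan <- exon_independence_scan(js, c(1, 10), model = energy_model())
  expect_equal(scan$fraction_intra[1], 1)   # exon alone: no pairs, flagged
  expect_true(scan$empty[1])
  expect_true(any(scan$fraction_intra < 1))
})

test_that("empty folds are flagged and report fraction 1 by convention", {
  js <- list(sequence = strrep("A", 20), junction_offset = 10L)
  scan <- exon_independence_scan(js, c(1, 10), model = energy_model())
  expect_true(all(scan$empty))
  expect_true(all(scan$fraction_intra == 1))
})
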