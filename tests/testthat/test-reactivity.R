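make_rate_table <- function(mutr_s, mutr_u, depth = 10000,
                            base = rep("A", length(mutr_s))) {
  data.frame(position = seq_along(mutr_s), base = base,
             mutr_s = mutr_s, mutr_u = mutr_u,
             depth_s = depth, depth_u = depth, stringsAsFactors = FALSE)
}

test_that("raw reactivity is the background-subtracted rate, negatives
           retained", {
  tab <- make_rate_table(c(0.05, 0.02, 0.004), c(0.01, 0.02, 0.010))
  prof <- compute_raw_reactivity(tab)
  expect_equal(prof$reactivity, c(0.04, 0, -0.006))
  # binomial SE propagation
  expect_equal(prof$se[1],
               sqrt(0.05 * 0.95 / 10000 + 0.01 * 0.99 / 10000))
  expect_error(compute_raw_reactivity(data.frame(position = 1)), "columns")
})

test_that("per-base normalization divides by the top-decile mean and is
           idempotent", {
  set.seed(5)
  vals <- rgamma(200, 2, scale = 0.4)
  prof <- data.frame(position = 1:200,
                     base = sample(c("A", "C", "G", "U"), 200, TRUE),
                     reactivity = vals, se = 0.01)
  norm <- normalize_per_base(prof)
  for (b in c("A", "C", "G", "U")) {
    v <- sort(norm$reactivity[norm$base == b], decreasing = TRUE)
    n <- length(v)
    n_excl <- floor(0.02 * n + 0.5)
    n_top <- max(1, floor(0.10 * n + 0.5))
    expect_equal(mean(v[(n_excl + 1):(n_excl + n_top)]), 1,
                 tolerance = 1e-9)
  }
  again <- normalize_per_base(norm)
  expect_equal(again$reactivity, norm$reactivity, tolerance = 1e-9)
  # 100 identical values normalize to exactly 1
  flat <- data.frame(position = 1:100, base = "A", reactivity = 0.37,
                     se = 0.01)
  expect_true(all(normalize_per_base(flat)$reactivity == 1))
})

test_that("sentinels pass through normalization untouched and sparse base
           types warn", {
  prof <- data.frame(position = 1:60,
                     base = c(rep("A", 50), rep("G", 10)),
                     reactivity = c(rep(0.5, 25), rep(-999, 25),
                                    rep(0.2, 5), rep(-999, 5)),
                     se = 0.01)
  expect_warning(norm <- normalize_per_base(prof), "fewer than 10")
  expect_true(all(norm$reactivity[26:50] == -999))
  expect_true(all(norm$reactivity[51:60] == -999))  # sparse G emitted as NA
})

test_that("visualization mode rescales G and U to a 0.1 maximum", {
  prof <- data.frame(position = 1:40,
                     base = rep(c("A", "G"), each = 20),
                     reactivity = c(rep(1, 20),
                                    rep(c(0.5, 0.25), 10)),
                     se = 0)
  norm <- normalize_per_base(prof, visualization_mode = TRUE)
  g <- norm$reactivity[norm$base == "G"]
  expect_equal(max(g), 0.1)
  expect_equal(sort(unique(g)), c(0.05, 0.1))
})

test_that("folding preparation masks G/U, caps at 5 and floors negatives", {
  prof <- data.frame(position = 1:4, base = c("A", "G", "C", "A"),
                     reactivity = c(7, 0.3, -0.2, 0.4), se = 0.01)
  ready <- prepare_for_folding(prof)
  expect_equal(ready$reactivity, c(5, -999, 0, 0.4))
})

# reference with many short helices so every context class is populated
tandem_structure <- function(n_units = 30, arm = 5, loop = 4, linker = 3,
                             seed = 1) {
  withr::with_seed(seed, {
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    chars <- character(0)
    pairs <- integer(0)
    for (u in seq_len(n_units)) {
      a <- sample(c("A", "C", "G", "U"), arm, replace = TRUE)
      unit <- c(a, sample(c("A", "C"), loop, TRUE), rev(comp[a]),
                sample(c("A", "C", "G", "U"), linker, TRUE))
      base <- length(chars)
      p <- integer(length(unit))
      p[1:arm] <- base + (2 * arm + loop):(arm + loop + 1)
      p[(arm + loop + 1):(2 * arm + loop)] <- base + arm:1
      chars <- c(chars, unit)
      pairs <- c(pairs, p)
    }
    secondary_structure(paste(chars, collapse = ""), pairs)
  })
}

test_that("context calibration recovers the simulated class means", {
  ref <- tandem_structure(seed = 21)
  params <- reactivity_sim_params(seed = 22)
  prof <- simulate_reactivities(ref, params)
  ctx <- calibrate_context_distributions(prof, ref)
  expect_false(ctx$merged)
  # class means within 4 standard errors of the generating means
  counts <- table(psifold:::classify_context(ref)[
    prof$base %in% c("A", "C")])
  for (cl in c("unpaired", "helix_end", "stacked")) {
    true_mean <- switch(cl, unpaired = params$unpaired_mean,
                        helix_end = params$helix_end_mean,
                        stacked = params$paired_mean)
    se <- true_mean / sqrt(params$dispersion) / sqrt(counts[[cl]])
    expect_lt(abs(ctx$means[[cl]] - true_mean), 4 * se)
  }
  expect_gt(ctx$means[["unpaired"]], ctx$means[["stacked"]])
})

test_that("sparse calibration classes merge into one paired density", {
  js <- gen_junction_sequence(40, 18, 5, seed = 23)
  prof <- simulate_reactivities(js$true_structure,
                                reactivity_sim_params(seed = 24))
  ctx <- calibrate_context_distributions(prof, js$true_structure)
  expect_true(ctx$merged)
  expect_identical(ctx$helix_end(0.3), ctx$stacked(0.3))
})

test_that("calibration fits on capped values only", {
  js <- gen_junction_sequence(200, 100, 20, seed = 25)
  prof <- simulate_reactivities(js$true_structure,
                                reactivity_sim_params(seed = 26))
  spiked <- prof
  up <- which(js$true_structure$pairs == 0 & prof$base %in% c("A", "C"))
  spiked$reactivity[up[1:5]] <- 50  # far above the cap
  a <- calibrate_context_distributions(spiked, js$true_structure)
  capped <- spiked
  capped$reactivity[up[1:5]] <- 5
  b <- calibrate_context_distributions(capped, js$true_structure)
  expect_equal(a$means, b$means)
})

test_that("reactivity AUC equals the Mann-Whitney statistic and hits its
           limits", {
  # toy: 3 unpaired, 3 paired A/C nucleotides
  ref <- secondary_structure("AACAAC", c(0L, 0L, 0L, 0L, 0L, 0L))
  ref$pairs <- c(6L, 5L, 0L, 0L, 2L, 1L)  # bypass min-hairpin for the toy
  prof <- data.frame(position = 1:6, base = "A",
                     reactivity = c(0.1, 0.3, 0.9, 0.8, 0.2, 0.5), se = 0)
  # brute-force rank count over (unpaired, paired) pairs
  un <- prof$reactivity[ref$pairs == 0]
  pa <- prof$reactivity[ref$pairs > 0]
  brute <- mean(outer(un, pa, ">") + 0.5 * outer(un, pa, "=="))
  expect_equal(reactivity_auc(prof, ref), brute)
  # perfect separation
  prof2 <- prof
  prof2$reactivity <- ifelse(ref$pairs == 0, 1, 0)
  expect_equal(reactivity_auc(prof2, ref), 1)
  # single-class reference is undefined
  open <- secondary_structure("AAAAAA")
  expect_error(reactivity_auc(prof, open), "single")
})

test_that("class-independent reactivities give AUC near one half", {
  js <- gen_junction_sequence(200, 100, 20, seed = 27)
  n <- nchar(js$sequence)
  prof <- withr::with_seed(28, data.frame(
    position = 1:n, base = strsplit(js$sequence, "")[[1]],
    reactivity = runif(n), se = 0))
  auc <- reactivity_auc(prof, js$true_structure)
  keep <- prof$base %in% c("A", "C")
  n1 <- sum(js$true_structure$pairs[keep] == 0)
  n0 <- sum(keep) - n1
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(auc - 0.5), 4 * se)
})

test_that(".map files round-trip a profile", {
  js <- fixture_junction()
  prof <- fixture_profile(js)
  path <- tempfile(fileext = ".map")
  write_map(prof, path)
  back <- read_map(path)
  expect_equal(back$reactivity, prof$reactivity)
  expect_equal(back$base, prof$base)
})

test_that("ShapeMapper-style profile tables round-trip", {
  tab <- make_rate_table(c(0.05, 0.01), c(0.01, 0.005),
                         base = c("A", "C"))
  path <- tempfile(fileext = ".txt")
  write_profile_table(tab, path)
  back <- read_profile_table(path)
  expect_equal(back$mutr_s, tab$mutr_s)
  expect_equal(back$depth_u, tab$depth_u)
})
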