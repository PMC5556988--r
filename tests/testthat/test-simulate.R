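test_that("ancestral elements carry perfect terminal inverted repeats", {
  for (seed in 1:5) {
    el <- make_ancestral_element(1300, 28, seed = seed)
    expect_equal(nchar(el$sequence), 1300)
    expect_identical(substr(el$sequence, 1, 28),
                     dna_revcomp(substr(el$sequence, 1273, 1300)))
    expect_false(el$is_mite)
  }
  # minimal element: one internal base between the TIRs
  el <- make_ancestral_element(57, 28, seed = 1)
  expect_equal(nchar(el$sequence), 57)
  expect_identical(substr(el$sequence, 1, 28),
                   dna_revcomp(substr(el$sequence, 30, 57)))
  expect_error(make_ancestral_element(50, 28), "tir_length")
})

test_that("MITE derivation keeps both ends and records the deletion", {
  el <- make_ancestral_element(1300, 28, seed = 2)
  mite <- derive_mite(el, keep5 = 275, keep3 = 275)
  expect_equal(nchar(mite$sequence), 550)
  expect_true(mite$is_mite)
  expect_identical(substr(mite$sequence, 1, 275), substr(el$sequence, 1, 275))
  expect_identical(substr(mite$sequence, 276, 550),
                   substr(el$sequence, 1026, 1300))
  expect_equal(mite$internal_deletion, c(275, 1025))
  # TIRs survive the deletion
  expect_identical(substr(mite$sequence, 1, 28),
                   dna_revcomp(substr(mite$sequence, 523, 550)))
  minimal <- derive_mite(el, keep5 = 28, keep3 = 28)
  expect_equal(nchar(minimal$sequence), 56)
  expect_error(derive_mite(el, keep5 = 700, keep3 = 700), "smaller")
  expect_error(derive_mite(el, keep5 = 10, keep3 = 275), "TIR length")
})

test_that("K2P evolution preserves length, is seeded, and inverts unbiasedly", {
  set.seed(10)
  anc <- random_dna(10000, 0.5)
  expect_identical(evolve_sequence(anc, 0), anc)
  e1 <- evolve_sequence(anc, 0.1, kappa = 2, seed = 3)
  e2 <- evolve_sequence(anc, 0.1, kappa = 2, seed = 3)
  e3 <- evolve_sequence(anc, 0.1, kappa = 2, seed = 4)
  expect_identical(e1, e2)
  expect_false(identical(e1, e3))
  expect_equal(nchar(e1), nchar(anc))
  expect_true(grepl("^[ACGT]+$", e1))
  expect_error(evolve_sequence(anc, -0.1), ">= 0")

  # estimated K2P of output vs input recovers the expected divergence
  res <- k2p(anc, e1)
  expect_gt(res$k, 0.09)
  expect_lt(res$k, 0.11)

  # transition fraction among substituted sites matches the two-rate process
  am <- strsplit(anc, "")[[1]]
  bm <- strsplit(e1, "")[[1]]
  diff <- am != bm
  ts_frac <- sum(diff & ((am %in% c("A", "G")) == (bm %in% c("A", "G")))) /
    sum(diff)
  # for kappa = 2 and d = 0.1 the exact P/(P+Q) is 0.491
  expect_lt(abs(ts_frac - 0.491), 3 * sqrt(0.25 / sum(diff)))

  # unbiasedness across divergences up to 0.3 (3 binomial SEs on 10-kb)
  for (d in c(0.05, 0.2, 0.3)) {
    ev <- evolve_sequence(anc, d, kappa = 2, seed = 100 + round(100 * d))
    se <- sqrt(d * (1 - d) / nchar(anc))
    expect_lt(abs(k2p(anc, ev)$k - d), 3 * se)
  }
})

test_that("planted copies match the truth table and carry TA duplications", {
  el <- make_ancestral_element(1300, 28, seed = 6)
  # age zero: genome slices at truth coordinates equal the element verbatim
  sim0 <- plant_copies(6e4, 0.42, el, ages = rep(0, 5), rate = 1.9e-3,
                       seed = 7)
  g <- sim0$genome[[1]]
  for (i in seq_len(nrow(sim0$truth))) {
    tr <- sim0$truth[i, ]
    planted <- substr(g, tr$start + 1, tr$end)
    if (tr$strand == "-") planted <- dna_revcomp(planted)
    expect_identical(planted, el$sequence)
    expect_identical(substr(g, tr$start - 1, tr$start), "TA")
    expect_identical(substr(g, tr$end + 1, tr$end + 2), "TA")
  }
  expect_identical(sim0$truth$class, rep("full_length", 5))

  # aged copies: mean copy-to-ancestor K2P recovers 2 * r * T
  sim <- plant_copies(3e5, 0.42, el, ages = rep(10, 50), rate = 1.9e-3,
                      seed = 8)
  ks <- vapply(seq_len(nrow(sim$truth)), function(i) {
    tr <- sim$truth[i, ]
    cp <- substr(sim$genome[[1]], tr$start + 1, tr$end)
    if (tr$strand == "-") cp <- dna_revcomp(cp)
    k2p(cp, el$sequence)$k
  }, numeric(1))
  d <- 2 * 1.9e-3 * 10
  se_mean <- sqrt(d * (1 - d) / 1300) / sqrt(50)
  expect_lt(abs(mean(ks) - d), 3 * se_mean)

  expect_error(plant_copies(5e3, 0.42, el, ages = rep(0, 5), rate = 1.9e-3),
               "half the genome")
})

test_that("invasion scenarios carry consistent truth labels and defaults", {
  cfg <- scenario_config(td = 90, th_a = 90, th_b = 25, n_copies = 5,
                         genome_length = 3e4, seed = 11)
  expect_equal(cfg$n_ortholog_pairs, 50)
  sim <- simulate_ht_scenario(cfg)
  expect_identical(sim$truth_label, "HT")
  expect_equal(nrow(sim$orthologs), 50)
  expect_equal(nrow(sim$truth$A), 5)
  expect_equal(nrow(sim$truth$B), 5)
  # determinism: same config gives byte-identical output
  sim2 <- simulate_ht_scenario(cfg)
  expect_identical(sim$genomes, sim2$genomes)
  expect_identical(sim$orthologs, sim2$orthologs)

  vert <- simulate_ht_scenario(scenario_config(td = 60, th_a = 60, th_b = 60,
                                               n_copies = 3,
                                               genome_length = 2e4,
                                               n_ortholog_pairs = 4,
                                               seed = 12))
  expect_identical(vert$truth_label, "vertical")

  expect_error(scenario_config(td = -1), "times")
  expect_error(scenario_config(rate = 0), "rate")
  expect_error(scenario_config(n_ortholog_pairs = 1), "ortholog")
})

test_that("truth tables and ortholog pairs round-trip through text formats", {
  el <- make_ancestral_element(200, 28, seed = 3)
  sim <- plant_copies(1e4, 0.5, el, ages = c(0, 5), rate = 2e-3, seed = 4)
  tdir <- withr::local_tempdir()
  p <- write_truth_table(sim$truth, file.path(tdir, "truth.tsv"))
  back <- read.table(p, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 2)
  expect_equal(back$start, sim$truth$start)

  cfg_file <- file.path(tdir, "scenario.cfg")
  writeLines(c("td = 90", "th_b = 25", "n_copies = 4", "seed = 5",
               "# a comment", "genome_length = 20000"), cfg_file)
  cfg <- read_scenario_config(cfg_file)
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$td, 90)
  expect_equal(cfg$n_copies, 4)
  writeLines("nonsense_key = 1", cfg_file)
  expect_error(read_scenario_config(cfg_file), "unknown config key")
})
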