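test_that("alignment handles identity, deletions and empty input", {
  set.seed(41)
  s <- random_dna(100, 0.5)
  aln <- pairwise_align(s, s, mode = "global")
  expect_equal(aln$score, 200)
  expect_identical(aln$a_aligned, s)
  expect_identical(aln$b_aligned, s)

  # a 5-bp internal deletion appears as a single gap in semiglobal mode
  del <- paste0(substr(s, 1, 50), substr(s, 56, 100))
  aln2 <- pairwise_align(s, del, mode = "semiglobal")
  gaps <- gregexpr("-+", aln2$b_aligned)[[1]]
  expect_equal(length(gaps), 1)
  expect_equal(attr(gaps, "match.length"), 5)
  expect_false(grepl("-", aln2$a_aligned))

  expect_error(pairwise_align("", "ACGT"), "non-empty")
})

test_that("global alignment scores match exhaustive enumeration", {
  set.seed(42)
  for (i in 1:100) {
    la <- sample(2:9, 1)
    lb <- sample(2:9, 1)
    a <- random_dna(la, 0.5)
    b <- random_dna(lb, 0.5)
    expect_equal(pairwise_align(a, b, mode = "global")$score,
                 enum_align_score(a, b),
                 info = paste(a, b))
  }
  # a few longer pairs at the full 12-bp size
  for (i in 1:5) {
    a <- random_dna(12, 0.5)
    b <- random_dna(12, 0.5)
    expect_equal(pairwise_align(a, b, mode = "global")$score,
                 enum_align_score(a, b))
  }
})

test_that("majority consensus follows the column-majority rule", {
  set.seed(43)
  s <- random_dna(200, 0.5)
  prof <- build_majority_consensus(rep(s, 5), s)
  expect_identical(prof$consensus, s)
  expect_equal(prof$n_copies, 5)

  # single disagreeing column: A,A,C -> A
  v1 <- s
  v2 <- s
  v3 <- substitute_at(s, 100)
  prof2 <- build_majority_consensus(c(v1, v2, v3), s)
  expect_identical(prof2$consensus, s)
  expect_equal(sum(prof2$profile$coverage < 1), 0)

  # consensus of the consensus is itself
  again <- build_majority_consensus(prof2$consensus, prof2$consensus)
  expect_identical(again$consensus, prof2$consensus)

  expect_error(build_majority_consensus(character(0), s), "at least one")
})

test_that("consensus reconstruction recovers a simulated ancestor", {
  set.seed(44)
  anc <- make_ancestral_element(1000, 28)$sequence
  copies <- vapply(1:20, function(i) evolve_sequence(anc, 0.05),
                   character(1))
  prof <- build_majority_consensus(copies, anc)
  aln <- pairwise_align(prof$consensus, anc, mode = "global")
  expect_gte(1 - p_distance(aln$a_aligned, aln$b_aligned), 0.99)

  # consensus sits closer to the ancestor than the average copy
  copies2 <- vapply(1:20, function(i) evolve_sequence(anc, 0.1),
                    character(1))
  prof2 <- build_majority_consensus(copies2, anc)
  k_cons <- k2p_aligned_pair(prof2$consensus, anc)$k
  k_copies <- vapply(copies2, function(cp) k2p(cp, anc)$k, numeric(1))
  expect_lt(k_cons, mean(k_copies))
})

test_that("a MITE-dominated family yields a MITE-length consensus", {
  set.seed(45)
  el <- make_ancestral_element(1300, 28)
  mite <- derive_mite(el, 275, 275)
  copies <- vapply(1:10, function(i) evolve_sequence(mite$sequence, 0.03),
                   character(1))
  prof <- build_majority_consensus(copies, el$sequence, min_coverage = 0.2)
  expect_lt(nchar(prof$consensus), 600)
  expect_gt(nchar(prof$consensus), 500)
})

test_that("K2P matches its closed form, symmetry and the p-distance bound", {
  expect_equal(k2p("ACGTACGTAC", "ACGTACGTAC")$k, 0)
  # 10 sites, 1 transition + 1 transversion: -0.5 ln(0.7 sqrt(0.8))
  a <- "ACGTACGTAC"
  b <- "GCGTACGAAC"   # A->G transition at 1, G->A? check: pos8 T->A transversion
  res <- k2p(a, b)
  expect_equal(res$P, 0.1)
  expect_equal(res$Q, 0.1)
  expect_equal(res$k, -0.5 * log(0.7 * sqrt(0.8)), tolerance = 1e-9)
  expect_equal(res$k, 0.2341, tolerance = 1e-4)
  expect_equal(k2p(b, a)$k, res$k)

  # pairwise deletion: gap and N columns excluded
  gp <- k2p("AC-TN", "ACGTA")
  expect_equal(gp$n_sites, 3)
  expect_error(k2p("----", "ACGT"), "usable")
  expect_error(k2p("ACGT", "ACG"), "equal length")

  # K2P >= p-distance on the same sites
  set.seed(46)
  for (i in 1:20) {
    x <- random_dna(500, 0.5)
    y <- evolve_sequence(x, runif(1, 0, 0.3))
    expect_gte(k2p(x, y)$k + 1e-12, p_distance(x, y))
  }
})

test_that("K2P agrees with the ape reference implementation", {
  set.seed(47)
  for (i in 1:50) {
    x <- random_dna(300, 0.5)
    y <- evolve_sequence(x, runif(1, 0.01, 0.4))
    expect_equal(k2p(x, y)$k, ape_k2p(x, y), tolerance = 1e-9)
  }
})

test_that("saturation is flagged, never returned as a silent NaN", {
  a <- strrep("A", 30)
  b <- strrep("G", 30)  # all transitions: P = 1
  res <- k2p(a, b)
  expect_identical(res$status, "saturated")
  expect_true(is.na(res$k))
  expect_warning(k2p_distance(a, b), "saturated")
})

test_that("divergence tables date every copy against the consensus", {
  set.seed(48)
  anc <- make_ancestral_element(1300, 28)$sequence
  copies <- vapply(1:10, function(i) evolve_sequence(anc, 0.038),
                   character(1))
  prof <- build_majority_consensus(copies, anc)
  div <- divergence_table(copies, prof, rate = 1.9e-3)
  expect_equal(nrow(div), 10)
  expect_true(all(div$status == "ok"))
  expect_equal(mean(div$age_My), 10, tolerance = 0.25)
  # identical copy dates to zero
  div0 <- divergence_table(anc, anc, rate = 1.9e-3)
  expect_equal(div0$k, 0)
  expect_equal(div0$age_My, 0)
})

test_that("neighbor joining solves the three-point formulas and additivity", {
  m3 <- matrix(c(0, 5, 6, 5, 0, 9, 6, 9, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- ape::read.tree(text = nj_tree(m3))
  expect_setequal(tree$tip.label, c("a", "b", "c"))
  expect_equal(sort(tree$edge.length), c(1, 4, 5))

  # additive 4-taxon matrix: NJ reconstructs the tree metric exactly
  m4 <- matrix(c(0, 3, 3.5, 4.5,
                 3, 0, 4.5, 5.5,
                 3.5, 4.5, 0, 4,
                 4.5, 5.5, 4, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  t4 <- ape::read.tree(text = nj_tree(m4))
  coph <- cophenetic(t4)[letters[1:4], letters[1:4]]
  expect_equal(unname(coph), unname(m4), tolerance = 1e-8)

  # equidistant taxa: deterministic output, no negative branch lengths
  me <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(me) <- 0
  expect_identical(nj_tree(me), nj_tree(me))
  expect_true(all(ape::read.tree(text = nj_tree(me))$edge.length >= 0))

  expect_error(nj_tree(m3[1:2, 1:2]), "3 taxa")
  bad <- m3
  bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
})

test_that("consensus distance matrices are symmetric with zero diagonal", {
  set.seed(49)
  anc <- random_dna(800, 0.5)
  seqs <- c(s1 = evolve_sequence(anc, 0.02), s2 = evolve_sequence(anc, 0.05),
            s3 = evolve_sequence(anc, 0.1))
  m <- consensus_distance_matrix(seqs)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_true(all(m >= 0))
  expect_gt(m["s1", "s3"], m["s1", "s2"])
})
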