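test_that("planted TIRs are recovered and degraded TIRs reported imperfect", {
  el <- make_ancestral_element(1300, 28, seed = 31)
  tir <- detect_tirs(el$sequence)
  expect_equal(nrow(tir), 1)
  expect_equal(tir$five_start, 0)
  expect_gte(tir$five_length, 28)
  # every column of the designed 28-bp repeat matches
  expect_lte(tir$mismatches, tir$five_length - 28)
  expect_gte(tir$identity, 0.9)

  # two interior substitutions in the 5' TIR: imperfect but found
  damaged <- substitute_at(el$sequence, c(10, 20))
  tir2 <- detect_tirs(damaged)
  expect_equal(nrow(tir2), 1)
  expect_gte(tir2$mismatches, 2)
  expect_gte(tir2$identity, 0.8)

  expect_error(detect_tirs("ACGTACGT"), "shorter")
})

test_that("TIR false-positive rate on random sequence stays below 5%", {
  set.seed(32)
  hits <- vapply(1:100, function(i) {
    nrow(detect_tirs(random_dna(1000, 0.5))) > 0
  }, logical(1))
  expect_lt(mean(hits), 0.05)
})

test_that("reverse-complementing a copy swaps its TIR ends", {
  el <- make_ancestral_element(1300, 28, seed = 33)
  fwd <- detect_tirs(el$sequence)
  rev <- detect_tirs(dna_revcomp(el$sequence))
  expect_equal(rev$mismatches, fwd$mismatches)
  expect_equal(rev$five_length, fwd$five_length)
  len <- 1300
  expect_equal(rev$five_start, len - (fwd$three_start + fwd$three_length))
  expect_equal(rev$three_start, len - (fwd$five_start + fwd$five_length))
})

test_that("TSD detection requires the duplication on both flanks", {
  expect_identical(detect_tsd("GGGGTA", "TACCCC"), "TA")
  expect_identical(detect_tsd("ggggta", "tacccc"), "TA")
  expect_identical(detect_tsd("GGGGGC", "TACCCC"), NA_character_)
  expect_identical(detect_tsd("GGGGTA", "CCCCCC"), NA_character_)
  expect_identical(detect_tsd("XACGT", "ACGTX", tsd = "ACGT"), "ACGT")
  expect_identical(detect_tsd("T", "TA"), NA_character_)
})

test_that("ORF finding honors the getorf threshold semantics", {
  set.seed(34)
  # construct a clean frame: no ATG or stop outside the designed ORF
  safe_codons <- c("CCT", "CCA", "CCG", "CCC", "GGA", "GGC")  # Pro/Gly only
  orf300 <- paste0("ATG", paste(sample(safe_codons, 299, TRUE), collapse = ""),
                   "TAA")
  prefix <- strrep("C", 30)   # no ATG, no stop in any register
  suffix <- strrep("C", 31)
  seq <- paste0(prefix, orf300, suffix)
  found <- find_orfs(seq, min_aa = 300)
  expect_equal(nrow(found), 1)
  expect_equal(found$aa_length, 300)
  expect_true(found$has_stop)
  expect_equal(found$end - found$start, 903)
  # the reported interval translates back to M...* exactly
  expect_identical(substr(seq, found$start + 1, found$start + 3), "ATG")
  expect_identical(substr(seq, found$end - 2, found$end), "TAA")
  # the boundary is strict: at min_aa = 301 the same ORF no longer qualifies
  expect_equal(nrow(find_orfs(seq, min_aa = 301)), 0)

  # a 500-bp sequence cannot host a 300-aa ORF
  expect_equal(nrow(find_orfs(random_dna(500, 0.5), min_aa = 300)), 0)

  # ambiguous bases never act as start or stop codons
  no_start <- sub("^ATG", "ANG", orf300)
  expect_equal(nrow(find_orfs(no_start, min_aa = 300)), 0)
  no_stop <- sub("TAA$", "TNA", orf300)
  open_orf <- find_orfs(no_stop, min_aa = 300)
  expect_equal(nrow(open_orf), 1)
  expect_false(open_orf$has_stop)
})

test_that("ORF finding agrees with a translation-based oracle", {
  set.seed(35)
  for (i in 1:100) {
    s <- random_dna(2000, 0.5)
    ours <- find_orfs(s, min_aa = 50)
    expect_equal(sort(ours$aa_length), orf_lengths_oracle(s, 50))
  }
})

test_that("functional classification partitions all TIR/ORF combinations", {
  cls <- classify_copy(
    tir_found = c(TRUE, TRUE, FALSE, FALSE),
    max_orf_aa = c(350, 0, 350, 0),
    length = c(1300, 560, 900, 300)
  )
  expect_equal(cls$functional_class,
               c("potential_autonomous", "potential_non_autonomous",
                 "potential_coding", "partial"))
  expect_equal(cls$size_class,
               c("full_length", "mite", "partial_size", "partial_size"))
  # the tie at exactly 300 aa counts as coding-capable
  tie <- classify_copy(TRUE, 300, 1300)
  expect_equal(tie$functional_class, "potential_autonomous")
  expect_equal(classify_copy(TRUE, 299, 1300)$functional_class,
               "potential_non_autonomous")
  # totality: every combination receives exactly one class
  grid <- expand.grid(tir = c(TRUE, FALSE), orf = c(0L, 299L, 300L, 500L))
  all_cls <- classify_copy(grid$tir, grid$orf, rep(1000, nrow(grid)))
  expect_false(any(is.na(all_cls$functional_class)))
  expect_true(all(all_cls$functional_class %in%
    c("potential_autonomous", "potential_non_autonomous",
      "potential_coding", "partial")))
  expect_error(classify_copy(TRUE, 0, -5), "non-negative")
})

test_that("conservation matrices reproduce closed-form information content", {
  cons <- conservation_matrix(c("AAC", "AGC", "ACT", "ATG"))
  # column 1: all A -> 2 bits
  expect_equal(cons$ic_bits[1], 2)
  # column 2: 25% each base -> 0 bits
  expect_equal(cons$ic_bits[2], 0)
  # two-state column at 50/50 -> 1 bit
  half <- conservation_matrix(c("A", "A", "C", "C"))
  expect_equal(half$ic_bits, 1)
  # gaps excluded from totals
  gapped <- conservation_matrix(c("A-", "A-", "AC", "A-"))
  expect_equal(gapped$n[2], 1)
  expect_equal(gapped$ic_bits[1], 2)
  # IC bounded in [0, 2] on random alignments
  set.seed(36)
  rnd <- conservation_matrix(replicate(8, random_dna(100, 0.3)))
  expect_true(all(rnd$ic_bits >= 0 & rnd$ic_bits <= 2))
  expect_error(conservation_matrix("ACGT"), "two segments")
  expect_error(conservation_matrix(c("ACGT", "ACG")), "equal length")
})

test_that("copy annotation integrates TIR, TSD, ORF and classes", {
  el <- make_ancestral_element(1300, 28, seed = 37)
  mite <- derive_mite(el, 275, 275)
  copies <- tibble::tibble(
    copy_id = c("full", "mite", "frag"),
    sequence = c(el$sequence, mite$sequence, substr(el$sequence, 200, 500)),
    flank5 = c("GGTA", "CCTA", "GGGG"),
    flank3 = c("TACC", "TAGG", "CCCC")
  )
  ann <- annotate_copies(copies)
  expect_equal(nrow(ann), 3)
  expect_equal(ann$tir_found, c(TRUE, TRUE, FALSE))
  expect_equal(ann$tsd, c("TA", "TA", NA))
  expect_equal(ann$functional_class,
               c("potential_non_autonomous", "potential_non_autonomous",
                 "partial"))
  expect_equal(ann$size_class, c("full_length", "mite", "partial_size"))
  # empty input keeps the schema
  expect_equal(nrow(annotate_copies(copies[0, ])), 0)
  expect_true("functional_class" %in% names(annotate_copies(copies[0, ])))
})
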