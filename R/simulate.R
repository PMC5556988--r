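#' @name simulate
#' @title Simulation of transposon families with known ground truth
#'
#' @description
#' The simulator emulates the core features of a Tc1-mariner invasion:
#' full-length elements of ~1300 bp with ~28-bp terminal inverted repeats
#' (TIRs), internally deleted MITE derivatives of ~500-600 bp, a TA
#' target-site duplication at every insertion, and copies diverged from
#' their ancestor under a Kimura two-parameter (K2P) substitution process.
#' A copy of age `T` My evolving at rate `r` substitutions/site/My receives
#' an expected `2 r T` substitutions per site, so that dating by
#' `T = k / (2 r)` inverts the generative process exactly.
#'
#' All operations draw from R's RNG; pass `seed` to make a call
#' reproducible, or leave it `NULL` to thread an outer seeded stream
#' through composite simulations.
NULL

new_element_model <- function(element_id, sequence, tir_length,
                              internal_deletion = NULL, is_mite = FALSE) {
  structure(
    list(element_id = element_id, sequence = sequence,
         tir_length = as.integer(tir_length),
         internal_deletion = internal_deletion, is_mite = isTRUE(is_mite)),
    class = "element_model"
  )
}

#' @export
print.element_model <- function(x, ...) {
  cat(sprintf("<element_model %s: %d bp, %d-bp TIRs%s>\n", x$element_id,
              nchar(x$sequence), x$tir_length,
              if (x$is_mite) ", MITE derivative" else ""))
  invisible(x)
}

#' Construct a random ancestral element with perfect TIRs
#'
#' Draws a random-composition element whose first `tir_length` bases are the
#' reverse complement of its last `tir_length` bases, the hallmark of
#' Tc1-mariner transposons.
#'
#' @param length Element length in bp (default 1300, the canonical mariner
#'   size). Must be at least `2 * tir_length + 1`.
#' @param tir_length TIR length in bp (default 28).
#' @param gc GC fraction of the element body.
#' @param seed Optional integer seed.
#' @param element_id Identifier stored on the model.
#' @return An `element_model` object.
#' @export
#' @examples
#' el <- make_ancestral_element(1300, 28, seed = 1)
#' substr(el$sequence, 1, 28) == dna_revcomp(substr(el$sequence, 1273, 1300))
make_ancestral_element <- function(length = 1300, tir_length = 28, gc = 0.5,
                                   seed = NULL, element_id = "element1") {
  if (length < 2 * tir_length + 1) {
    abort(sprintf("length (%d) must be at least 2 * tir_length + 1 = %d",
                  length, 2 * tir_length + 1))
  }
  if (!is.null(seed)) set.seed(seed)
  tir5 <- random_dna(tir_length, gc)
  body <- random_dna(length - 2 * tir_length, gc)
  seq <- paste0(tir5, body, dna_revcomp(tir5))
  new_element_model(element_id, seq, tir_length)
}

#' Derive a MITE from a full-length element
#'
#' MITEs (miniature inverted-repeat transposable elements) are internally
#' deleted derivatives that keep both element ends, including the TIRs. The
#' derivative keeps the first `keep5` and last `keep3` bases.
#'
#' @param element An `element_model`.
#' @param keep5,keep3 Bases retained at the 5' and 3' ends; each must be at
#'   least the TIR length and their sum less than the element length.
#' @return An `element_model` with `is_mite = TRUE` and the deletion interval
#'   recorded as a 0-based half-open interval on the parent element.
#' @export
derive_mite <- function(element, keep5 = 275, keep3 = 275) {
  stopifnot(inherits(element, "element_model"))
  len <- nchar(element$sequence)
  if (keep5 < element$tir_length || keep3 < element$tir_length) {
    abort("keep5 and keep3 must each be at least the TIR length")
  }
  if (keep5 + keep3 >= len) {
    abort("keep5 + keep3 must be smaller than the element length")
  }
  seq <- paste0(substr(element$sequence, 1, keep5),
                substr(element$sequence, len - keep3 + 1, len))
  new_element_model(paste0(element$element_id, "_mite"), seq,
                    element$tir_length,
                    internal_deletion = c(keep5, len - keep3), is_mite = TRUE)
}

# K2P transition (P) and transversion (Q) probabilities after expected
# divergence d with transition/transversion rate ratio kappa = alpha/beta.
k2p_event_probs <- function(d, kappa) {
  stopifnot(d >= 0, kappa > 0)
  bt <- d / (kappa + 2)      # beta * t
  at <- kappa * bt           # alpha * t
  P <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  Q <- 0.5 - 0.5 * exp(-4 * bt)
  c(P = P, Q = Q)
}

#' Evolve a sequence under the Kimura two-parameter process
#'
#' Applies the exact K2P site-substitution probabilities for an expected
#' total divergence of `expected_divergence` substitutions per site, with
#' transition/transversion rate ratio `kappa`. Length is preserved
#' (substitution-only process); non-ACGT characters are left untouched.
#'
#' @param seq DNA string.
#' @param expected_divergence Expected substitutions per site (>= 0).
#' @param kappa Transition/transversion rate ratio alpha/beta (default 2).
#' @param seed Optional integer seed.
#' @return The mutated DNA string.
#' @export
evolve_sequence <- function(seq, expected_divergence, kappa = 2, seed = NULL) {
  seq <- as_single_seq(seq)
  if (expected_divergence < 0) abort("expected_divergence must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (expected_divergence == 0 || nchar(seq) == 0) return(seq)
  pq <- k2p_event_probs(expected_divergence, kappa)
  ch <- seq_chars(seq)
  u <- runif(length(ch))
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  transversions_of <- list(A = c("C", "T"), G = c("C", "T"),
                           C = c("A", "G"), T = c("A", "G"))
  acgt <- ch %in% c("A", "C", "G", "T")
  ts <- acgt & u < pq["P"]
  tv <- acgt & u >= pq["P"] & u < pq["P"] + pq["Q"]
  if (any(ts)) ch[ts] <- transition_of[ch[ts]]
  if (any(tv)) {
    pick <- runif(sum(tv)) < 0.5
    ch[tv] <- vapply(seq_len(sum(tv)), function(i) {
      transversions_of[[ch[tv][i]]][if (pick[i]) 1L else 2L]
    }, character(1))
  }
  paste(ch, collapse = "")
}

#' Plant diverged element copies into a random host genome
#'
#' Each copy is evolved independently from the element with expected
#' divergence `2 * rate * age` (so that `T = k / (2 r)` dating recovers the
#' planted age), inserted at a random non-overlapping position on a random
#' strand, and flanked by a duplicated TA target site: the 5' flank of every
#' copy ends with `TA` and its 3' flank starts with `TA`.
#'
#' @param genome_length Background genome length in bp before insertions.
#' @param gc GC fraction of the background.
#' @param element An `element_model` to amplify.
#' @param ages Numeric vector of copy ages in My (one copy per entry).
#' @param rate Substitution rate in substitutions/site/My.
#' @param kappa Transition/transversion rate ratio.
#' @param seed Optional integer seed.
#' @param tsd Target-site duplication string (default `"TA"`).
#' @param min_gap Minimum spacing between insertion sites in bp.
#' @param contig_id Name for the single simulated contig.
#' @return A list with `genome` (named character vector), `truth` (tibble of
#'   copy_id, contig, start, end, strand, age_My, class, element_id; 0-based
#'   half-open coordinates covering exactly the mutated copy), and `element`.
#' @export
plant_copies <- function(genome_length, gc = 0.42, element, ages, rate,
                         kappa = 2, seed = NULL, tsd = "TA", min_gap = 400,
                         contig_id = "contig1") {
  stopifnot(inherits(element, "element_model"))
  if (any(ages < 0)) abort("ages must be >= 0")
  if (rate <= 0) abort("rate must be > 0")
  if (!is.null(seed)) set.seed(seed)
  elen <- nchar(element$sequence)
  n <- length(ages)
  if (n * (elen + 2 * nchar(tsd)) >= genome_length / 2) {
    abort("total planted length must stay below half the genome length")
  }
  background <- random_dna(genome_length, gc)

  # insertion points on the background, separated by at least min_gap
  pos <- integer(0)
  tries <- 0
  while (length(pos) < n) {
    cand <- sample.int(genome_length - 1, 1)
    if (all(abs(cand - pos) >= min_gap + elen)) {
      pos <- c(pos, cand)
    }
    tries <- tries + 1
    if (tries > 1000 * n) {
      abort("could not place copies without overlap; reduce copy number or min_gap")
    }
  }
  pos <- sort(pos)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  copies <- vapply(ages, function(a) {
    evolve_sequence(element$sequence, 2 * rate * a, kappa)
  }, character(1))
  planted <- ifelse(strand == "+", copies, dna_revcomp(copies))

  pieces <- character(2 * n + 1)
  truth_start <- integer(n)
  prev <- 0
  offset <- 0
  for (i in seq_len(n)) {
    pieces[2 * i - 1] <- substr(background, prev + 1, pos[i])
    pieces[2 * i] <- paste0(tsd, planted[i], tsd)
    truth_start[i] <- pos[i] + offset + nchar(tsd)
    offset <- offset + nchar(planted[i]) + 2 * nchar(tsd)
    prev <- pos[i]
  }
  pieces[2 * n + 1] <- substr(background, prev + 1, genome_length)
  genome <- paste(pieces, collapse = "")

  truth <- tibble(
    copy_id = sprintf("%s_copy%03d", contig_id, seq_len(n)),
    contig = contig_id,
    start = truth_start,
    end = truth_start + nchar(planted),
    strand = strand,
    age_My = as.numeric(ages),
    class = if (element$is_mite) "mite" else "full_length",
    element_id = element$element_id
  )
  list(genome = setNames(genome, contig_id), truth = truth, element = element)
}

#' Scenario configuration for two-lineage invasion simulations
#'
#' Bundles the parameters of a vertical-vs-horizontal invasion scenario:
#' host lineages split `td` My ago; the element invaded lineage A `th_a` My
#' ago and lineage B `th_b` My ago. Per-gene substitution-rate multipliers
#' are lognormal with log-sd `rate_sigma`, reproducing the spread-with-tail
#' shape of empirical host-gene divergence distributions.
#'
#' @param td Host lineage split time in My.
#' @param th_a,th_b Element invasion ages per lineage in My (<= `td` for a
#'   horizontal transfer; equal to `td` for the vertical control).
#' @param rate Substitution rate (substitutions/site/My).
#' @param kappa Transition/transversion rate ratio.
#' @param n_copies Copies planted per lineage.
#' @param n_ortholog_pairs Single-copy ortholog pairs (default 50).
#' @param genome_length,gc Background genome size and composition.
#' @param gene_length Ortholog coding-sequence length in bp.
#' @param rate_sigma Log-sd of per-gene rate multipliers.
#' @param element_length,tir_length Element geometry.
#' @param seed RNG seed for the whole scenario.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(td = 90, th_a = 90, th_b = 25, rate = 1.9e-3,
                            kappa = 2, n_copies = 20, n_ortholog_pairs = 50,
                            genome_length = 1e5, gc = 0.42, gene_length = 1500,
                            rate_sigma = 0.25, element_length = 1300,
                            tir_length = 28, seed = 1) {
  cfg <- list(td = td, th_a = th_a, th_b = th_b, rate = rate, kappa = kappa,
              n_copies = n_copies, n_ortholog_pairs = n_ortholog_pairs,
              genome_length = genome_length, gc = gc,
              gene_length = gene_length, rate_sigma = rate_sigma,
              element_length = element_length, tir_length = tir_length,
              seed = seed)
  if (any(c(cfg$td, cfg$th_a, cfg$th_b) < 0)) abort("times must be >= 0")
  if (cfg$rate <= 0) abort("rate must be > 0")
  if (cfg$kappa <= 0) abort("kappa must be > 0")
  if (cfg$n_ortholog_pairs < 2) abort("n_ortholog_pairs must be >= 2")
  structure(cfg, class = "scenario_config")
}

#' Simulate a two-lineage invasion scenario
#'
#' Generates two host genomes whose element families descend from a common
#' ancestral element. The lineage-specific founder elements diverge from
#' each other by an expected `2 * rate * min(th_a, th_b)` substitutions per
#' site (the age of the more recent invasion governs how long the two
#' element pools have evolved apart), while ortholog pairs diverge by
#' `2 * rate * td` scaled by lognormal per-gene multipliers. The scenario is
#' labelled `"HT"` when the more recent invasion post-dates the host split,
#' `"vertical"` otherwise.
#'
#' @param config A [scenario_config()].
#' @return A list with `genomes` (named character vectors A and B), `truth`
#'   (per-lineage truth tibbles), `orthologs` (tibble of gene_id, seq_a,
#'   seq_b, rate_multiplier), `elements` (ancestral and founder models),
#'   `truth_label` and `config`.
#' @export
simulate_ht_scenario <- function(config = scenario_config()) {
  if (!inherits(config, "scenario_config")) config <- do.call(scenario_config, config)
  set.seed(config$seed)
  ancestor <- make_ancestral_element(config$element_length, config$tir_length,
                                     gc = config$gc)
  t_te <- min(config$th_a, config$th_b)
  founder_a <- new_element_model("founderA",
    evolve_sequence(ancestor$sequence, config$rate * t_te, config$kappa),
    config$tir_length)
  founder_b <- new_element_model("founderB",
    evolve_sequence(ancestor$sequence, config$rate * t_te, config$kappa),
    config$tir_length)

  sim_a <- plant_copies(config$genome_length, config$gc, founder_a,
                        ages = rep(config$th_a, config$n_copies),
                        rate = config$rate, kappa = config$kappa,
                        contig_id = "lineageA")
  sim_b <- plant_copies(config$genome_length, config$gc, founder_b,
                        ages = rep(config$th_b, config$n_copies),
                        rate = config$rate, kappa = config$kappa,
                        contig_id = "lineageB")

  mult <- rlnorm(config$n_ortholog_pairs, 0, config$rate_sigma)
  orthologs <- purrr::map_dfr(seq_len(config$n_ortholog_pairs), function(g) {
    anc <- random_dna(config$gene_length, config$gc)
    d_half <- config$rate * config$td * mult[g]
    tibble(
      gene_id = sprintf("gene%03d", g),
      seq_a = evolve_sequence(anc, d_half, config$kappa),
      seq_b = evolve_sequence(anc, d_half, config$kappa),
      rate_multiplier = mult[g]
    )
  })

  list(
    genomes = list(A = sim_a$genome, B = sim_b$genome),
    truth = list(A = sim_a$truth, B = sim_b$truth),
    orthologs = orthologs,
    elements = list(ancestral = ancestor, A = founder_a, B = founder_b),
    truth_label = if (t_te < config$td) "HT" else "vertical",
    config = config
  )
}

#' Write a simulation truth table as TSV
#'
#' @param truth Truth tibble from [plant_copies()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ortholog pairs as paired FASTA files
#'
#' @param orthologs Tibble from [simulate_ht_scenario()].
#' @param path_a,path_b Output FASTA paths for the two species.
#' @return Invisibly, the two paths.
#' @export
write_ortholog_pairs <- function(orthologs, path_a, path_b) {
  write_fasta(setNames(orthologs$seq_a, orthologs$gene_id), path_a)
  write_fasta(setNames(orthologs$seq_b, orthologs$gene_id), path_b)
  invisible(c(path_a, path_b))
}

#' Read a flat key=value scenario configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values are coerced to numeric where possible.
#'
#' @param path Config file path.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) abort(paste0("malformed config line: ", lines[bad][1]))
  vals <- lapply(kv, function(p) {
    v <- utils::type.convert(p[2], as.is = TRUE)
    v
  })
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) abort(paste0("unknown config keys: ",
                                    paste(unknown, collapse = ", ")))
  do.call(scenario_config, vals)
}
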