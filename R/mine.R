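#' Seed-and-extend homology search for element copies
#'
#' Re-implementation of a blastn-style nucleotide search: exact
#' `word_size`-mers shared between query and genome seed ungapped X-drop
#' extensions on both strands; extension clusters that could plausibly reach
#' the E-value cutoff are refined by gapped (affine, local) dynamic
#' programming in a window around the hit; the Karlin-Altschul expectation
#' `E = K m n exp(-lambda S)` is computed with lambda solved numerically
#' from the scoring scheme and the genome's base composition (gapped scores
#' reuse the ungapped lambda and K, a documented approximation). Only HSPs
#' with `E <= e_max` are returned.
#'
#' @param genome Named character vector of contig sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @param query Query consensus sequence (string, `DNAString(Set)` or FASTA
#'   path). Must be at least `word_size` long.
#' @param word_size Seed word size (default 11, the blastn default).
#' @param match,mismatch Match reward and mismatch penalty (defaults +2/-3).
#' @param gap_open,gap_extend Affine gap costs (defaults 5 and 2).
#' @param x_drop Ungapped extension X-drop in raw score units.
#' @param e_max E-value cutoff (default 1e-10).
#' @param refine_pad Bases of genomic context added around an ungapped
#'   extension before gapped refinement.
#' @param prefilter_log10_margin Ungapped extensions whose E-value exceeds
#'   `e_max` by more than this many orders of magnitude are discarded
#'   without gapped refinement.
#' @return Tibble of HSPs with 0-based half-open coordinates: `contig`,
#'   `qstart`, `qend` (query coordinates), `sstart`, `send` (genomic,
#'   forward-strand), `strand`, `score`, `length`, `nmatch`, `identity`
#'   (percent), `evalue`, `log10_evalue`, `bit_score`.
#' @export
te_search <- function(genome, query, word_size = 11, match = 2, mismatch = -3,
                      gap_open = 5, gap_extend = 2, x_drop = 40,
                      e_max = 1e-10, refine_pad = 200,
                      prefilter_log10_margin = 6) {
  genome <- as_genome_chars(genome)
  query <- as_single_seq(query, "query")
  qlen <- nchar(query)
  if (qlen < word_size) abort("query is shorter than the seed word size")
  n_total <- sum(nchar(genome))
  base_counts <- Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(genome), baseOnly = TRUE)
  bf <- colSums(base_counts)[c("A", "C", "G", "T")]
  bf <- if (sum(bf) > 0) bf / sum(bf) else rep(0.25, 4)
  ka <- karlin_altschul_params(match, mismatch, bf)
  log10_cut <- log10(e_max)

  empty <- tibble(contig = character(), qstart = integer(), qend = integer(),
                  sstart = integer(), send = integer(), strand = character(),
                  score = numeric(), length = integer(), nmatch = integer(),
                  identity = numeric(), evalue = numeric(),
                  log10_evalue = numeric(), bit_score = numeric())

  queries <- c("+" = query, "-" = dna_revcomp(query))
  out <- list()
  for (contig in names(genome)) {
    subject <- genome[[contig]]
    for (strand in c("+", "-")) {
      q <- queries[[strand]]
      seeds <- seed_hits_cpp(q, subject, word_size)
      if (nrow(seeds) == 0) next
      ext <- as_tibble(ungapped_extend_cpp(q, subject, seeds[, 1], seeds[, 2],
                                           word_size, match, mismatch, x_drop))
      ext <- dplyr::distinct(ext, .data$qstart, .data$qend, .data$sstart,
                             .data$send, .keep_all = TRUE)
      # cluster overlapping extensions on the subject; keep best per cluster
      ir <- IRanges::IRanges(start = ext$sstart + 1L, end = ext$send)
      red <- IRanges::reduce(ir, with.revmap = TRUE)
      keep <- vapply(S4Vectors::mcols(red)$revmap, function(idx) {
        idx[which.max(ext$score[idx])]
      }, integer(1))
      ext <- ext[keep, , drop = FALSE]
      # prefilter on the ungapped score
      log10_e <- (log(ka$K) + log(qlen) + log(n_total) -
                    ka$lambda * ext$score) / log(10)
      ext <- ext[log10_e <= log10_cut + prefilter_log10_margin, , drop = FALSE]
      if (nrow(ext) == 0) next
      # gapped refinement in a padded window
      refined <- purrr::map_dfr(seq_len(nrow(ext)), function(i) {
        ws <- max(0L, ext$sstart[i] - refine_pad)
        we <- min(nchar(subject), ext$send[i] + refine_pad)
        aln <- affine_align_cpp(q, substr(subject, ws + 1, we), match,
                                mismatch, gap_open, gap_extend, 2L)
        cols <- nchar(aln$a_aligned)
        if (cols == 0) return(NULL)
        am <- seq_chars(aln$a_aligned)
        bm <- seq_chars(aln$b_aligned)
        nmatch <- sum(am == bm & am != "-")
        rc_qs <- aln$a_start
        rc_qe <- aln$a_end
        tibble(
          qstart = if (strand == "+") rc_qs else qlen - rc_qe,
          qend = if (strand == "+") rc_qe else qlen - rc_qs,
          sstart = ws + aln$b_start,
          send = ws + aln$b_end,
          score = aln$score,
          length = cols,
          nmatch = nmatch
        )
      })
      if (is.null(refined) || nrow(refined) == 0) next
      refined$contig <- contig
      refined$strand <- strand
      out[[length(out) + 1]] <- refined
    }
  }
  if (length(out) == 0) return(empty)
  hsps <- bind_rows(out)
  ev <- alignment_evalue(hsps$score, qlen, n_total, ka)
  hsps$identity <- 100 * hsps$nmatch / hsps$length
  hsps$evalue <- ev$evalue
  hsps$log10_evalue <- ev$log10_evalue
  hsps$bit_score <- ev$bit_score
  hsps <- hsps[hsps$log10_evalue <= log10_cut, , drop = FALSE]
  hsps <- dplyr::arrange(hsps, .data$contig, .data$sstart, .data$send)
  dplyr::select(hsps, dplyr::all_of(names(empty)))
}

#' Merge HSPs into copy loci
#'
#' Same-contig, same-strand HSPs whose genomic intervals overlap or lie
#' within `max_gap` bp of each other are merged into a single locus (one
#' element copy can yield several HSPs when its middle has decayed). Each
#' locus inherits the best (lowest) E-value and best score of its HSPs.
#'
#' @param hsps Tibble from [te_search()].
#' @param max_gap Maximum merge distance in bp (default 100).
#' @return Tibble of loci: `locus_id`, `contig`, `start`, `end`, `strand`,
#'   `n_hsps`, `score`, `evalue`, `log10_evalue`.
#' @export
merge_hits <- function(hsps, max_gap = 100) {
  empty <- tibble(locus_id = character(), contig = character(),
                  start = integer(), end = integer(), strand = character(),
                  n_hsps = integer(), score = numeric(), evalue = numeric(),
                  log10_evalue = numeric())
  if (nrow(hsps) == 0) return(empty)
  merged <- hsps |>
    group_by(.data$contig, .data$strand) |>
    arrange(.data$sstart, .by_group = TRUE) |>
    mutate(new_block = cumsum(
      .data$sstart > dplyr::lag(cummax(as.numeric(.data$send)),
                                default = -Inf) + max_gap
    )) |>
    group_by(.data$contig, .data$strand, .data$new_block) |>
    summarise(
      start = min(.data$sstart), end = max(.data$send),
      n_hsps = dplyr::n(), score = max(.data$score),
      evalue = min(.data$evalue), log10_evalue = min(.data$log10_evalue),
      .groups = "drop"
    ) |>
    arrange(.data$contig, .data$start, .data$strand)
  merged$locus_id <- sprintf("locus%04d", seq_len(nrow(merged)))
  dplyr::select(merged, dplyr::all_of(names(empty)))
}

#' Extract copy sequences with flanking context
#'
#' Retrieves each locus sequence plus up to `flank` bp of genomic context on
#' either side. Minus-strand copies are reverse-complemented so that the
#' returned `sequence`, `flank5` and `flank3` read in element orientation
#' while `start`/`end` stay genomic. Flanks hitting a contig edge are
#' truncated and flagged.
#'
#' @param genome Genome as for [te_search()].
#' @param loci Tibble from [merge_hits()] (columns contig, start, end,
#'   strand; `locus_id` used for copy ids when present).
#' @param flank Flank length in bp (default 200).
#' @return Tibble of copies: `copy_id`, `contig`, `start`, `end`, `strand`,
#'   `sequence`, `flank5`, `flank3`, `flank5_truncated`, `flank3_truncated`.
#' @export
extract_copies <- function(genome, loci, flank = 200) {
  genome <- as_genome_chars(genome)
  empty <- tibble(copy_id = character(), contig = character(),
                  start = integer(), end = integer(), strand = character(),
                  sequence = character(), flank5 = character(),
                  flank3 = character(), flank5_truncated = logical(),
                  flank3_truncated = logical())
  if (nrow(loci) == 0) return(empty)
  ids <- if ("locus_id" %in% names(loci)) {
    sub("^locus", "copy", loci$locus_id)
  } else {
    sprintf("copy%04d", seq_len(nrow(loci)))
  }
  purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    contig <- loci$contig[i]
    if (!contig %in% names(genome)) abort(paste0("unknown contig: ", contig))
    cs <- genome[[contig]]
    clen <- nchar(cs)
    s <- loci$start[i]; e <- loci$end[i]
    if (s < 0 || e > clen || s >= e) abort("locus outside contig bounds")
    left_s <- max(0, s - flank)
    right_e <- min(clen, e + flank)
    seq <- substr(cs, s + 1, e)
    left <- substr(cs, left_s + 1, s)
    right <- substr(cs, e + 1, right_e)
    minus <- identical(loci$strand[i], "-")
    tibble(
      copy_id = ids[i], contig = contig, start = s, end = e,
      strand = loci$strand[i],
      sequence = if (minus) dna_revcomp(seq) else seq,
      flank5 = if (minus) dna_revcomp(right) else left,
      flank3 = if (minus) dna_revcomp(left) else right,
      flank5_truncated = if (minus) nchar(right) < flank else nchar(left) < flank,
      flank3_truncated = if (minus) nchar(left) < flank else nchar(right) < flank
    )
  })
}

#' Write loci as BED6
#'
#' @param loci Tibble from [merge_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(loci, path) {
  bed <- data.frame(loci$contig, loci$start, loci$end, loci$locus_id,
                    round(loci$score), loci$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write HSPs as a TSV with identity and E-value columns
#'
#' @param hsps Tibble from [te_search()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hsps, path) {
  out <- hsps
  out$identity <- round(out$identity, 1)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write copies (and flanks) as FASTA with structured headers
#'
#' Headers take the form `copy_id|contig|start-end|strand`.
#'
#' @param copies Tibble from [extract_copies()].
#' @param path Output path.
#' @param include_flanks Concatenate flanks around each copy sequence.
#' @return `path`, invisibly.
#' @export
write_copies_fasta <- function(copies, path, include_flanks = FALSE) {
  headers <- sprintf("%s|%s|%d-%d|%s", copies$copy_id, copies$contig,
                     copies$start, copies$end, copies$strand)
  seqs <- if (include_flanks) {
    paste0(copies$flank5, copies$sequence, copies$flank3)
  } else {
    copies$sequence
  }
  write_fasta(setNames(seqs, headers), path)
}
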