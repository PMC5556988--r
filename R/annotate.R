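#' Detect terminal inverted repeats
#'
#' Scans the first `window` bases of a copy against the reverse complement
#' of its last `window` bases for the best ungapped inverted repeat with
#' length in `[min_len, max_len]` and identity at least `min_identity`.
#' "Best" maximises the number of matching bases, with ties broken toward
#' longer repeats and then outermost (smallest-offset) placement.
#'
#' @param copy_seq Copy sequence.
#' @param min_len,max_len Allowed TIR length range in bp (defaults 20-40,
#'   bracketing the ~28-bp mariner TIR).
#' @param min_identity Minimum repeat identity (default 0.8, admitting the
#'   imperfect TIRs typical of old copies).
#' @param window Bases searched at each terminus (default 60).
#' @return One-row tibble (`five_start`, `five_length`, `three_start`,
#'   `three_length`, `mismatches`, `identity`; 0-based starts on the copy)
#'   or a zero-row tibble when no repeat qualifies.
#' @export
detect_tirs <- function(copy_seq, min_len = 20, max_len = 40,
                        min_identity = 0.8, window = 60) {
  copy_seq <- as_single_seq(copy_seq, "copy_seq")
  len <- nchar(copy_seq)
  if (len < 2 * min_len) abort("sequence shorter than twice the minimum TIR length")
  w <- min(window, floor(len / 2))
  prefix <- substr(copy_seq, 1, w)
  rc_suffix <- dna_revcomp(substr(copy_seq, len - w + 1, len))
  hit <- best_inverted_repeat_cpp(prefix, rc_suffix, min_len, max_len,
                                  min_identity)
  empty <- tibble(five_start = integer(), five_length = integer(),
                  three_start = integer(), three_length = integer(),
                  mismatches = integer(), identity = numeric())
  if (!isTRUE(hit$found)) return(empty)
  tibble(
    five_start = hit$i, five_length = hit$length,
    three_start = len - hit$j - hit$length, three_length = hit$length,
    mismatches = hit$mismatches, identity = hit$identity
  )
}

#' Detect a target-site duplication
#'
#' Reports `tsd` iff the 5' flank ends with it and the 3' flank starts with
#' it (case-insensitive). The TA duplication is the hallmark of mariner
#' insertions.
#'
#' @param flank5,flank3 Flanking sequences in element orientation.
#' @param tsd Expected duplication (default `"TA"`).
#' @return The TSD string, or `NA_character_` when absent.
#' @export
detect_tsd <- function(flank5, flank3, tsd = "TA") {
  if (is.na(flank5) || is.na(flank3) || nchar(flank5) < nchar(tsd) ||
      nchar(flank3) < nchar(tsd)) {
    return(NA_character_)
  }
  up <- toupper(tsd)
  ok <- endsWith(toupper(flank5), up) && startsWith(toupper(flank3), up)
  if (ok) up else NA_character_
}

#' Six-frame open reading frame search
#'
#' Scans all six frames for ATG-to-stop spans, reporting translations of at
#' least `min_aa` residues. Follows getorf semantics: `min_aa` applies to
#' the translated peptide excluding the stop codon; an ORF still open at the
#' end of the sequence is reported without a stop. Codons containing
#' ambiguous bases translate to X and never act as start or stop.
#'
#' @param seq DNA string.
#' @param min_aa Minimum peptide length in residues (default 300,
#'   i.e. `-minsize 900` in nucleotides).
#' @param require_methionine Require an ATG start (default TRUE; ORFs begin
#'   at the first ATG after the previous stop).
#' @return Tibble with `frame` (+1..+3, -1..-3), `start`, `end` (0-based
#'   half-open on the forward strand, including the stop codon when
#'   present), `aa_length`, `starts_with_methionine`, `has_stop`.
#' @export
find_orfs <- function(seq, min_aa = 300, require_methionine = TRUE) {
  seq <- as_single_seq(seq)
  len <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  scan_frame <- function(s, offset, frame_label, on_reverse) {
    slen <- nchar(s)
    n_codon <- (slen - offset) %/% 3
    if (n_codon < 1) return(NULL)
    starts_nt <- offset + 3 * (seq_len(n_codon) - 1)        # 0-based
    codons <- substring(s, starts_nt + 1, starts_nt + 3)
    orf_open <- FALSE
    orf_start <- NA_integer_
    recs <- list()
    flush <- function(start_nt, end_nt, has_stop) {
      aa_len <- if (has_stop) (end_nt - start_nt - 3) / 3 else (end_nt - start_nt) / 3
      if (aa_len < min_aa) return(NULL)
      fwd <- if (on_reverse) c(len - end_nt, len - start_nt) else c(start_nt, end_nt)
      tibble(frame = frame_label, start = fwd[1], end = fwd[2],
             aa_length = as.integer(aa_len),
             starts_with_methionine = require_methionine,
             has_stop = has_stop)
    }
    for (i in seq_len(n_codon)) {
      cd <- codons[i]
      if (cd %in% stops) {
        if (orf_open) {
          recs[[length(recs) + 1]] <- flush(orf_start, starts_nt[i] + 3, TRUE)
        }
        orf_open <- FALSE
      } else if (!orf_open) {
        if (!require_methionine || cd == "ATG") {
          orf_open <- TRUE
          orf_start <- starts_nt[i]
        }
      }
    }
    if (orf_open) {
      recs[[length(recs) + 1]] <- flush(orf_start, starts_nt[n_codon] + 3, FALSE)
    }
    recs <- recs[!vapply(recs, is.null, logical(1))]
    if (length(recs)) bind_rows(recs) else NULL
  }
  for (f in 0:2) out[[length(out) + 1]] <- scan_frame(seq, f, f + 1L, FALSE)
  rc <- dna_revcomp(seq)
  for (f in 0:2) out[[length(out) + 1]] <- scan_frame(rc, f, -(f + 1L), TRUE)
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(tibble(frame = integer(), start = integer(), end = integer(),
                  aa_length = integer(), starts_with_methionine = logical(),
                  has_stop = logical()))
  }
  arrange(bind_rows(out), desc(.data$aa_length), .data$frame, .data$start)
}

#' Classify a copy into functional and size classes
#'
#' Functional classes follow the four-way rule: (i) conserved TIRs and an
#' ORF of at least `min_orf_aa` residues make a copy potential_autonomous;
#' (ii) TIRs without such an ORF, potential_non_autonomous; (iii) an ORF
#' without TIRs, potential_coding; (iv) neither, partial. Ties at exactly
#' `min_orf_aa` residues count as coding-capable. Size classes follow
#' length bands: full_length (1200-1400 bp), mite (450-650 bp), otherwise
#' partial_size.
#'
#' @param tir_found Logical; conserved TIRs present.
#' @param max_orf_aa Longest ORF in residues (0 when none).
#' @param length Copy length in bp.
#' @param min_orf_aa Coding threshold in residues (default 300).
#' @param full_length_band,mite_band Inclusive length bands in bp.
#' @return Tibble with `functional_class` and `size_class` (vectorised over
#'   the inputs).
#' @export
classify_copy <- function(tir_found, max_orf_aa, length, min_orf_aa = 300,
                          full_length_band = c(1200, 1400),
                          mite_band = c(450, 650)) {
  if (any(length < 0)) abort("length must be non-negative")
  coding <- max_orf_aa >= min_orf_aa
  functional <- dplyr::case_when(
    tir_found & coding ~ "potential_autonomous",
    tir_found & !coding ~ "potential_non_autonomous",
    !tir_found & coding ~ "potential_coding",
    TRUE ~ "partial"
  )
  size <- dplyr::case_when(
    length >= full_length_band[1] & length <= full_length_band[2] ~ "full_length",
    length >= mite_band[1] & length <= mite_band[2] ~ "mite",
    TRUE ~ "partial_size"
  )
  tibble(functional_class = functional, size_class = size)
}

#' Annotate mined copies
#'
#' Runs TIR, TSD and ORF detection on every copy and applies the four-way
#' functional classification plus size bands.
#'
#' @param copies Tibble from [extract_copies()] (or any tibble with
#'   `copy_id`, `sequence` and optional `flank5`/`flank3` columns).
#' @param tsd Expected target-site duplication.
#' @param min_tir_len,max_tir_len,min_tir_identity,tir_window TIR detection
#'   parameters, see [detect_tirs()].
#' @param min_orf_aa Coding threshold in residues.
#' @param require_methionine Passed to [find_orfs()].
#' @param full_length_band,mite_band Size bands, see [classify_copy()].
#' @return Tibble with one row per copy: `copy_id`, `length`, `tir_found`,
#'   `tir_length`, `tir_identity`, `tsd`, `max_orf_aa`, `n_orfs`,
#'   `functional_class`, `size_class`.
#' @export
annotate_copies <- function(copies, tsd = "TA", min_tir_len = 20,
                            max_tir_len = 40, min_tir_identity = 0.8,
                            tir_window = 60, min_orf_aa = 300,
                            require_methionine = TRUE,
                            full_length_band = c(1200, 1400),
                            mite_band = c(450, 650)) {
  has_flanks <- all(c("flank5", "flank3") %in% names(copies))
  if (nrow(copies) == 0) {
    return(tibble(copy_id = character(), length = integer(),
                  tir_found = logical(), tir_length = integer(),
                  tir_identity = numeric(), tsd = character(),
                  max_orf_aa = integer(), n_orfs = integer(),
                  functional_class = character(), size_class = character()))
  }
  ann <- purrr::map_dfr(seq_len(nrow(copies)), function(i) {
    s <- copies$sequence[i]
    len <- nchar(s)
    tir <- if (len >= 2 * min_tir_len) {
      detect_tirs(s, min_tir_len, max_tir_len, min_tir_identity, tir_window)
    } else {
      tibble(five_start = integer(), five_length = integer(),
             three_start = integer(), three_length = integer(),
             mismatches = integer(), identity = numeric())
    }
    orfs <- find_orfs(s, min_aa = min_orf_aa,
                      require_methionine = require_methionine)
    tibble(
      copy_id = copies$copy_id[i],
      length = len,
      tir_found = nrow(tir) == 1,
      tir_length = if (nrow(tir)) tir$five_length else NA_integer_,
      tir_identity = if (nrow(tir)) tir$identity else NA_real_,
      tsd = if (has_flanks) detect_tsd(copies$flank5[i], copies$flank3[i], tsd)
            else NA_character_,
      max_orf_aa = if (nrow(orfs)) max(orfs$aa_length) else 0L,
      n_orfs = nrow(orfs)
    )
  })
  cls <- classify_copy(ann$tir_found, ann$max_orf_aa, ann$length,
                       min_orf_aa, full_length_band, mite_band)
  bind_rows(cbind(ann, cls))
}

#' Per-column base frequencies and information content
#'
#' Numeric stand-in for a sequence logo: per-column counts and frequencies
#' over A/C/G/T (gaps and ambiguous bases are excluded from the column
#' total) and information content `IC = 2 + sum f log2 f` bits, without
#' small-sample correction.
#'
#' @param aligned_segments Character vector of at least two equal-length
#'   (aligned) DNA segments.
#' @return Tibble with `position` (1-based), counts `A`, `C`, `G`, `T`,
#'   `n` (non-gap total) and `ic_bits`.
#' @export
conservation_matrix <- function(aligned_segments) {
  if (length(aligned_segments) < 2) abort("need at least two segments")
  lens <- nchar(aligned_segments)
  if (length(unique(lens)) != 1) abort("segments must have equal lengths")
  mat <- do.call(rbind, strsplit(toupper(aligned_segments), ""))
  purrr::map_dfr(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    counts <- vapply(c("A", "C", "G", "T"), function(b) sum(col == b), integer(1))
    n <- sum(counts)
    ic <- if (n > 0) {
      f <- counts[counts > 0] / n
      2 + sum(f * log2(f))
    } else {
      NA_real_
    }
    tibble(position = j, A = counts[["A"]], C = counts[["C"]],
           G = counts[["G"]], T = counts[["T"]], n = n, ic_bits = ic)
  })
}

#' Write per-copy annotations as TSV
#'
#' @param annotations Tibble from [annotate_copies()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotations, path) {
  out <- annotations
  out$tir_identity <- round(out$tir_identity, 3)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a conservation matrix as TSV
#'
#' @param cons Tibble from [conservation_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(cons, path) {
  out <- cons
  out$ic_bits <- round(out$ic_bits, 4)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
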