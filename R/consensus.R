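#' Majority consensus from element copies via star alignment
#'
#' Every copy is aligned semiglobally to a reference (typically the query
#' consensus, or the longest copy) and the pairwise alignments are stacked
#' into a star alignment: columns are reference positions, plus insertion
#' columns retained when more than `min_insert_support` of the copies carry
#' a base there. Per column, the consensus base is the most frequent
#' non-gap base (ties broken alphabetically); a gap wins only if the gap
#' count strictly exceeds every base count. Columns whose non-gap coverage
#' falls below `min_coverage` are dropped from the consensus sequence (so a
#' family of internally deleted MITEs yields a MITE-length consensus), but
#' remain visible in the profile.
#'
#' @param copies Character vector of copy sequences, or a tibble with
#'   `sequence` (and optionally `copy_id`) columns. At least one copy; a
#'   single copy returns itself (consensus building is idempotent).
#' @param reference Reference sequence the star is built on.
#' @param min_coverage Minimum fraction of copies with a non-gap base for a
#'   column to be emitted (default 0.2).
#' @param min_insert_support Fraction of copies that must support an
#'   insertion column (default 0.5, exclusive).
#' @param species_id Optional label stored on the profile.
#' @param match,mismatch,gap_open,gap_extend Alignment scoring scheme. The
#'   default gap costs (12 to open, 0.25 per base) are deliberately
#'   long-deletion-tolerant: MITE derivatives differ from the full-length
#'   element by internal deletions of hundreds of bp, which per-base gap
#'   extension costs in the blastn range would price out of the optimal
#'   alignment entirely.
#' @return A `consensus_profile`: list with `species_id`, `consensus`,
#'   `n_copies` and `profile` (per-column tibble of counts over A/C/G/T/gap,
#'   coverage, consensus base and whether the column was emitted).
#' @export
build_majority_consensus <- function(copies, reference, min_coverage = 0.2,
                                     min_insert_support = 0.5,
                                     species_id = NA_character_, match = 2,
                                     mismatch = -3, gap_open = 12,
                                     gap_extend = 0.25) {
  if (is.data.frame(copies)) copies <- copies$sequence
  copies <- vapply(copies, as_single_seq, character(1), USE.NAMES = FALSE)
  n <- length(copies)
  if (n < 1) abort("need at least one copy")
  reference <- as_single_seq(reference, "reference")
  L <- nchar(reference)
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = 5, ncol = L,
                   dimnames = list(c(bases, "gap"), NULL))
  inserts <- new.env(parent = emptyenv())

  for (cp in copies) {
    aln <- affine_align_cpp(cp, reference, match, mismatch, gap_open,
                            gap_extend, 1L)
    am <- seq_chars(aln$a_aligned)
    bm <- seq_chars(aln$b_aligned)
    is_ref <- bm != "-"
    ref_pos <- cumsum(is_ref)           # 1-based ref position at ref columns
    # reference columns
    a_ref <- am[is_ref]
    p_ref <- ref_pos[is_ref]
    bi <- match(a_ref, bases)
    for (k in 1:4) {
      sel <- which(bi == k)
      if (length(sel)) {
        tab <- tabulate(p_ref[sel], nbins = L)
        counts[k, ] <- counts[k, ] + tab
      }
    }
    gap_sel <- which(a_ref == "-")
    if (length(gap_sel)) {
      counts[5, ] <- counts[5, ] + tabulate(p_ref[gap_sel], nbins = L)
    }
    # insertion columns (copy base against reference gap)
    ins_idx <- which(!is_ref & am != "-")
    if (length(ins_idx)) {
      run <- cumsum(c(TRUE, diff(ins_idx) != 1))
      off <- stats::ave(ins_idx, run, FUN = seq_along)
      keys <- paste0(ref_pos[ins_idx], ":", off)
      for (t in seq_along(ins_idx)) {
        key <- keys[t]
        cur <- if (exists(key, envir = inserts)) get(key, envir = inserts)
               else setNames(integer(4), bases)
        b <- am[ins_idx[t]]
        if (b %in% bases) {
          cur[b] <- cur[b] + 1L
          assign(key, cur, envir = inserts)
        }
      }
    }
  }

  ref_profile <- tibble(
    ref_pos = seq_len(L), insertion_offset = 0L,
    A = counts[1, ], C = counts[2, ], G = counts[3, ], T = counts[4, ],
    gap = n - (counts[1, ] + counts[2, ] + counts[3, ] + counts[4, ])
  )
  ins_keys <- ls(inserts)
  ins_profile <- if (length(ins_keys)) {
    purrr::map_dfr(ins_keys, function(key) {
      cur <- get(key, envir = inserts)
      if (sum(cur) <= min_insert_support * n) return(NULL)
      parts <- as.integer(strsplit(key, ":", fixed = TRUE)[[1]])
      tibble(ref_pos = parts[1], insertion_offset = parts[2],
             A = cur[["A"]], C = cur[["C"]], G = cur[["G"]], T = cur[["T"]],
             gap = n - sum(cur))
    })
  } else {
    NULL
  }
  profile <- bind_rows(ref_profile, ins_profile) |>
    arrange(.data$ref_pos, .data$insertion_offset)

  base_mat <- as.matrix(profile[, c("A", "C", "G", "T")])
  top <- apply(base_mat, 1, max)
  winner <- bases[apply(base_mat, 1, which.max)]   # which.max: alphabetical tie-break
  non_gap <- rowSums(base_mat)
  gap_wins <- profile$gap > top
  profile$coverage <- non_gap / n
  profile$consensus_base <- ifelse(gap_wins | non_gap == 0, "-", winner)
  profile$emitted <- profile$coverage >= min_coverage & !gap_wins & non_gap > 0
  profile$column <- seq_len(nrow(profile))
  profile <- dplyr::relocate(profile, "column")

  consensus <- paste(profile$consensus_base[profile$emitted], collapse = "")
  structure(
    list(species_id = species_id, consensus = consensus, n_copies = n,
         profile = profile),
    class = "consensus_profile"
  )
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("<consensus_profile%s: %d copies, consensus %d bp (%d columns)>\n",
              if (is.na(x$species_id)) "" else paste0(" ", x$species_id),
              x$n_copies, nchar(x$consensus), nrow(x$profile)))
  invisible(x)
}

#' @export
tidy.consensus_profile <- function(x, ...) x$profile

#' @export
glance.consensus_profile <- function(x, ...) {
  tibble(species_id = x$species_id, n_copies = x$n_copies,
         consensus_length = nchar(x$consensus), n_columns = nrow(x$profile))
}

#' Write a consensus sequence as FASTA
#'
#' @param profile A `consensus_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(profile, path) {
  id <- if (is.na(profile$species_id)) "consensus" else
    paste0(profile$species_id, "_consensus")
  write_fasta(setNames(profile$consensus, id), path)
}
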