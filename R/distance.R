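#' Kimura two-parameter distance between aligned sequences
#'
#' With P the transition fraction and Q the transversion fraction over
#' usable sites, returns `d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))`. Sites
#' where either row carries a gap or an ambiguous base are excluded
#' (pairwise deletion, as in distmat). When the logarithm's argument is
#' non-positive the distance is saturated: `k` is `NA` and `status` is
#' `"saturated"` rather than a silent NaN.
#'
#' @param a,b Aligned (possibly gapped) sequences of equal length.
#' @return One-row tibble: `k`, `P`, `Q`, `n_sites`, `status` (`"ok"` or
#'   `"saturated"`).
#' @export
#' @examples
#' k2p("ACGTACGTAC", "GCGTACGAAC")  # one transition, one transversion
k2p <- function(a, b) {
  a <- toupper(as_single_seq(a, "a"))
  b <- toupper(as_single_seq(b, "b"))
  if (nchar(a) != nchar(b)) abort("aligned sequences must have equal length")
  am <- seq_chars(a)
  bm <- seq_chars(b)
  usable <- am %in% c("A", "C", "G", "T") & bm %in% c("A", "C", "G", "T")
  n <- sum(usable)
  if (n == 0) abort("no usable (ungapped, unambiguous) sites")
  am <- am[usable]
  bm <- bm[usable]
  diff <- am != bm
  ts <- diff & is_transition_pair(am, bm)
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    return(tibble(k = NA_real_, P = P, Q = Q, n_sites = n,
                  status = "saturated"))
  }
  tibble(k = -0.5 * log(arg1 * sqrt(arg2)), P = P, Q = Q, n_sites = n,
         status = "ok")
}

#' @rdname k2p
#' @return `k2p_distance()` returns the distance as a bare numeric scalar
#'   (`NA` with a warning when saturated).
#' @export
k2p_distance <- function(a, b) {
  res <- k2p(a, b)
  if (res$status == "saturated") {
    warn("K2P distance is saturated (log argument <= 0); returning NA")
  }
  res$k
}

#' K2P distance between two unaligned sequences
#'
#' Aligns the pair with [pairwise_align()] and applies [k2p()].
#'
#' @param a,b DNA strings.
#' @param mode Alignment mode (default `"semiglobal"`, appropriate when one
#'   sequence may be an internally deleted derivative of the other).
#' @param gap_open,gap_extend Affine gap costs. Defaults are
#'   long-deletion-tolerant (12 to open, 0.25 per base) so that the
#'   hundreds-of-bp internal deletions of MITE derivatives are bridged by a
#'   gap instead of being forced through mismatch-saturated columns, which
#'   would inflate the distance.
#' @param ... Further scoring parameters passed to [pairwise_align()].
#' @return One-row tibble as for [k2p()].
#' @export
k2p_aligned_pair <- function(a, b, mode = "semiglobal", gap_open = 12,
                             gap_extend = 0.25, ...) {
  aln <- pairwise_align(a, b, mode = mode, gap_open = gap_open,
                        gap_extend = gap_extend, ...)
  k2p(aln$a_aligned, aln$b_aligned)
}

#' Copy-to-consensus divergence table
#'
#' Aligns every copy to its species consensus and reports the K2P distance
#' `k` per copy; saturated copies are flagged via `status`, never dropped.
#' When `rate` is supplied, ages `T = k / (2 rate)` are added.
#'
#' @param copies Character vector of copy sequences or tibble with
#'   `copy_id` and `sequence` columns.
#' @param profile A `consensus_profile` (or a single consensus string).
#' @param rate Optional substitution rate (substitutions/site/My).
#' @param mode Alignment mode (default `"semiglobal"`).
#' @return Tibble with one row per copy: `copy_id`, `k`, `P`, `Q`,
#'   `n_sites`, `status` and, with `rate`, `age_My`.
#' @export
divergence_table <- function(copies, profile, rate = NULL,
                             mode = "semiglobal") {
  if (is.data.frame(copies)) {
    ids <- copies$copy_id
    seqs <- copies$sequence
  } else {
    ids <- if (!is.null(names(copies))) names(copies)
           else sprintf("copy%04d", seq_along(copies))
    seqs <- unname(copies)
  }
  consensus <- if (inherits(profile, "consensus_profile")) profile$consensus
               else as_single_seq(profile, "consensus")
  out <- purrr::map_dfr(seq_along(seqs), function(i) {
    res <- k2p_aligned_pair(seqs[i], consensus, mode = mode)
    res$copy_id <- ids[i]
    res
  })
  out <- dplyr::relocate(out, "copy_id")
  if (!is.null(rate)) out$age_My <- age_from_divergence(out$k, rate)
  out
}

#' Pairwise K2P distance matrix between consensus sequences
#'
#' @param seqs Named character vector of consensus sequences, or a list of
#'   `consensus_profile` objects.
#' @param mode Alignment mode (default `"semiglobal"`).
#' @param ... Scoring parameters passed to [pairwise_align()].
#' @return Symmetric numeric matrix with zero diagonal. Saturated pairs
#'   come back as `NA`.
#' @export
consensus_distance_matrix <- function(seqs, mode = "semiglobal", ...) {
  if (is.list(seqs) && all(vapply(seqs, inherits, logical(1), "consensus_profile"))) {
    nm <- vapply(seqs, function(p) p$species_id, character(1))
    seqs <- setNames(vapply(seqs, function(p) p$consensus, character(1)), nm)
  }
  stopifnot(is.character(seqs), length(seqs) >= 2)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      res <- k2p_aligned_pair(seqs[[i]], seqs[[j]], mode = mode, ...)
      m[i, j] <- m[j, i] <- res$k
    }
  }
  m
}

#' Write a distance matrix as TSV
#'
#' Labels in the first row and column; the lower triangle mirrors the
#' upper.
#'
#' @param m Symmetric matrix from [consensus_distance_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(m, path) {
  df <- data.frame(species = rownames(m), round(m, 4), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Neighbor-joining tree from a K2P distance matrix
#'
#' Thin clustering utility over the standard neighbor-joining algorithm
#' (Q-criterion, via ape). Negative branch lengths are clamped to zero.
#' Intended as a quick clustering view of consensus distances, not as a
#' maximum-likelihood phylogeny.
#'
#' @param m Symmetric distance matrix with at least 3 labelled taxa.
#' @return Newick string (rooted arbitrarily, unrooted topology).
#' @export
nj_tree <- function(m) {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    abort("distance matrix must be symmetric")
  }
  if (nrow(m) < 3) abort("need at least 3 taxa")
  if (any(is.na(m))) abort("distance matrix contains NA (saturated pairs?)")
  tree <- ape::nj(stats::as.dist(m))
  tree$edge.length[tree$edge.length < 0] <- 0
  ape::write.tree(tree)
}
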