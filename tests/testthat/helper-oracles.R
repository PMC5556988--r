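# Independent oracles and small fixture builders used across the suite.

# Exhaustive affine-gap global alignment score by recursive enumeration of
# all alignments (with an optimistic branch-and-bound so 12-bp pairs stay
# feasible). Deliberately independent of the package's DP implementation.
enum_align_score <- function(a, b, match = 2, mismatch = -3, gap_open = 5,
                             gap_extend = 2) {
  am <- strsplit(a, "")[[1]]
  bm <- strsplit(b, "")[[1]]
  na <- length(am)
  nb <- length(bm)
  best <- -Inf
  rec <- function(i, j, sc, state) {
    ra <- na - i
    rb <- nb - j
    if (sc + match * min(ra, rb) < best) return(invisible(NULL))
    if (ra == 0 && rb == 0) {
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (ra > 0 && rb > 0) {
      s <- if (am[i + 1] == bm[j + 1]) match else mismatch
      rec(i + 1, j + 1, sc + s, 0L)
    }
    if (ra > 0) {
      rec(i + 1, j, sc - gap_extend - if (state == 1L) 0 else gap_open, 1L)
    }
    if (rb > 0) {
      rec(i, j + 1, sc - gap_extend - if (state == 2L) 0 else gap_open, 2L)
    }
    invisible(NULL)
  }
  rec(0L, 0L, 0, 0L)
  best
}

# p-distance over usable (ungapped ACGT) sites of an aligned pair
p_distance <- function(a, b) {
  am <- strsplit(a, "")[[1]]
  bm <- strsplit(b, "")[[1]]
  ok <- am %in% c("A", "C", "G", "T") & bm %in% c("A", "C", "G", "T")
  sum(am[ok] != bm[ok]) / sum(ok)
}

# K2P oracle via ape on two equal-length ungapped strings
ape_k2p <- function(a, b) {
  m <- rbind(strsplit(tolower(a), "")[[1]], strsplit(tolower(b), "")[[1]])
  as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "K80",
                           pairwise.deletion = TRUE))
}

# Best local alignment score oracle via Biostrings (same scoring scheme as
# the package defaults)
biostrings_local_score <- function(query, subject, match = 2, mismatch = -3,
                                   gap_open = 5, gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(query, subject, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = gap_open,
                                gapExtension = gap_extend,
                                scoreOnly = TRUE)
}

# Brute-force six-frame ORF oracle built on Biostrings translation: returns
# the multiset of ORF peptide lengths (first ATG after each stop, >= min_aa)
orf_lengths_oracle <- function(seq, min_aa) {
  lens <- integer(0)
  for (s in c(seq, tepaleo::dna_revcomp(seq))) {
    n <- nchar(s)
    for (off in 0:2) {
      ncod <- (n - off) %/% 3
      if (ncod < 1) next
      sub <- substr(s, off + 1, off + 3 * ncod)
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                               if.fuzzy.codon = "X",
                                               no.init.codon = TRUE))
      segs <- strsplit(aa, "*", fixed = TRUE)[[1]]
      ends_with_stop <- c(rep(TRUE, length(segs) - 1),
                          !endsWith(aa, "*"))
      # an aa string ending in "*" drops the trailing empty segment in strsplit
      if (endsWith(aa, "*")) ends_with_stop <- rep(TRUE, length(segs))
      for (k in seq_along(segs)) {
        mpos <- regexpr("M", segs[k], fixed = TRUE)
        if (mpos > 0) {
          l <- nchar(segs[k]) - mpos + 1
          if (l >= min_aa) lens <- c(lens, l)
        }
      }
    }
  }
  sort(lens)
}

# substitute bases at given 1-based positions (cyclic A->C->G->T->A, so the
# result always differs)
substitute_at <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  ch[positions] <- chartr("ACGT", "CGTA", ch[positions])
  paste(ch, collapse = "")
}

# fraction of truth copies recovered by loci with >= min_overlap reciprocal
# coverage of the truth interval
planted_recall <- function(loci, truth, min_overlap = 0.8) {
  if (nrow(truth) == 0) return(NA_real_)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    len <- truth$end[i] - truth$start[i]
    same <- loci$contig == truth$contig[i]
    if (!any(same)) return(FALSE)
    ov <- pmin(loci$end[same], truth$end[i]) -
      pmax(loci$start[same], truth$start[i])
    any(ov >= min_overlap * len)
  }, logical(1))
  mean(hit)
}
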