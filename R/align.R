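#' Pairwise affine-gap alignment
#'
#' Optimal pairwise alignment under match/mismatch scoring with affine gap
#' costs (a gap of length L costs `gap_open + L * gap_extend`), via
#' three-state dynamic programming. `"global"` aligns both sequences end to
#' end, `"semiglobal"` leaves terminal gaps unpenalized (used for aligning
#' partial copies to a full-length reference), `"local"` returns the best
#' Smith-Waterman subalignment.
#'
#' @param a,b DNA strings.
#' @param match,mismatch,gap_open,gap_extend Scoring scheme (defaults
#'   +2/-3, 5/2, mirroring blastn).
#' @param mode One of `"global"`, `"semiglobal"`, `"local"`.
#' @return A `pairwise_alignment`: list with `score`, `a_aligned`,
#'   `b_aligned` (gapped strings of equal length), `mode`, and for local
#'   mode the 0-based half-open aligned intervals `a_start`/`a_end`,
#'   `b_start`/`b_end`.
#' @export
#' @examples
#' pairwise_align("ACGTACGT", "ACGTCGT", mode = "global")$score
pairwise_align <- function(a, b, match = 2, mismatch = -3, gap_open = 5,
                           gap_extend = 2,
                           mode = c("global", "semiglobal", "local")) {
  mode <- match.arg(mode)
  a <- as_single_seq(a, "a")
  b <- as_single_seq(b, "b")
  if (nchar(a) == 0 || nchar(b) == 0) abort("sequences must be non-empty")
  res <- affine_align_cpp(a, b, match, mismatch, gap_open, gap_extend,
                          match(mode, c("global", "semiglobal", "local")) - 1L)
  structure(c(res, list(mode = mode)), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment (%s): score %.1f, %d columns>\n",
              x$mode, x$score, nchar(x$a_aligned)))
  invisible(x)
}

#' @export
tidy.pairwise_alignment <- function(x, ...) {
  am <- seq_chars(x$a_aligned)
  bm <- seq_chars(x$b_aligned)
  tibble(
    column = seq_along(am), a = am, b = bm,
    match = am == bm & am != "-",
    gap = am == "-" | bm == "-"
  )
}
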