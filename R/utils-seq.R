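#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement preserving case and IUPAC ambiguity codes.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' dna_revcomp("ACGTTA")
dna_revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' Random DNA sequence
#'
#' Draws an i.i.d. DNA sequence with a given GC fraction, using the current
#' RNG state (seed management is left to the caller so that composite
#' simulations stay reproducible from a single seed).
#'
#' @param length Sequence length in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @return A single character string.
#' @export
random_dna <- function(length, gc = 0.5) {
  stopifnot(length >= 0, gc >= 0, gc <= 1)
  if (length == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

# Normalise genome input: named character vector, DNAStringSet, or FASTA path.
as_genome_chars <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else if (is.character(genome) && length(genome) == 1 && file.exists(genome) &&
             !grepl("^[ACGTNacgtn]+$", genome)) {
    out <- as.character(Biostrings::readDNAStringSet(genome))
  } else if (is.character(genome)) {
    out <- genome
  } else {
    abort("genome must be a named character vector, a DNAStringSet, or a FASTA path")
  }
  if (length(out) == 0) abort("genome contains no sequences")
  if (is.null(names(out)) || any(names(out) == "")) {
    names(out) <- paste0("contig", seq_along(out))
  }
  # keep only the first whitespace-delimited token of FASTA headers
  names(out) <- sub("\\s.*$", "", names(out))
  toupper(out)
}

as_single_seq <- function(x, what = "sequence") {
  if (inherits(x, "DNAString") || inherits(x, "DNAStringSet")) x <- as.character(x)
  if (is.character(x) && length(x) == 1 && file.exists(x) &&
      !grepl("^[ACGTNacgtn]+$", x)) {
    x <- as.character(Biostrings::readDNAStringSet(x))
  }
  if (!is.character(x) || length(x) != 1) {
    abort(paste0(what, " must be a single DNA string"))
  }
  toupper(unname(x))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @param width Line wrap width (default 80 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80) {
  stopifnot(is.character(seqs))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file (gzip-compressed files are handled transparently).
#' @return Named character vector, headers clipped at the first whitespace.
#' @export
read_fasta <- function(path) {
  as_genome_chars(Biostrings::readDNAStringSet(path))
}

# split a DNA string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

is_transition_pair <- function(a, b) {
  (a %in% PURINES & b %in% PURINES) | (a %in% PYRIMIDINES & b %in% PYRIMIDINES)
}
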