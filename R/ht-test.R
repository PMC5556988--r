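#' Horizontal-transfer quantile test
#'
#' Compares the divergence of two species' element consensus sequences
#' against the divergence distribution of single-copy host orthologs. A
#' vertically inherited, neutrally evolving element should be at least as
#' divergent as typical host genes; an element much less divergent than the
#' host-gene bulk indicates horizontal transfer. The exceedance fraction is
#' the proportion of genes strictly more divergent than the element (ties
#' count against horizontal transfer). The call is three-way: `"HT"` when
#' the fraction reaches `threshold`; `"vertical"` when it sits within the
#' gene bulk (`[lower, threshold)`); `"inconclusive"` below `lower`, i.e.
#' when the element is *more* divergent than most genes, which is flagged
#' rather than silently called vertical.
#'
#' @param te_distance K2P distance between the two element consensuses.
#' @param gene_distances K2P distances of single-copy ortholog pairs (at
#'   least 2, no NA).
#' @param threshold Exceedance fraction at or above which HT is called
#'   (default 0.90).
#' @param lower Lower bound of the vertical band (default 0.25).
#' @return An `ht_test` object: list with `te_distance`, `gene_distances`,
#'   `n_genes`, `n_genes_greater`, `fraction_greater`, `threshold`,
#'   `lower`, `call`.
#' @export
#' @examples
#' ht_quantile_test(0.05, c(0.2, 0.25, 0.3, 0.35))
ht_quantile_test <- function(te_distance, gene_distances, threshold = 0.90,
                             lower = 0.25) {
  if (length(gene_distances) < 2) abort("need at least 2 gene distances")
  if (any(is.na(gene_distances)) || is.na(te_distance)) {
    abort("distances must not contain NA (handle saturated pairs upstream)")
  }
  stopifnot(threshold > lower, lower >= 0, threshold <= 1)
  n <- length(gene_distances)
  n_greater <- sum(gene_distances > te_distance)
  frac <- n_greater / n
  call <- if (frac >= threshold) "HT"
          else if (frac >= lower) "vertical"
          else "inconclusive"
  structure(
    list(te_distance = te_distance, gene_distances = gene_distances,
         n_genes = n, n_genes_greater = n_greater, fraction_greater = frac,
         threshold = threshold, lower = lower, call = call),
    class = "ht_test"
  )
}

#' @export
print.ht_test <- function(x, ...) {
  cat(sprintf(paste0("<ht_test: TE K2P %.4f vs %d genes; %d (%.0f%%) genes ",
                     "more divergent; call: %s>\n"),
              x$te_distance, x$n_genes, x$n_genes_greater,
              100 * x$fraction_greater, x$call))
  invisible(x)
}

#' @export
tidy.ht_test <- function(x, ...) {
  tibble(gene = seq_along(x$gene_distances),
         gene_distance = x$gene_distances,
         greater_than_te = x$gene_distances > x$te_distance)
}

#' @export
glance.ht_test <- function(x, ...) {
  tibble(te_distance = x$te_distance, n_genes = x$n_genes,
         n_genes_greater = x$n_genes_greater,
         fraction_greater = x$fraction_greater, threshold = x$threshold,
         lower = x$lower, call = x$call)
}

#' @export
autoplot.ht_test <- function(object, ...) {
  df <- tibble(gene_distance = object$gene_distances)
  ggplot(df, aes(x = .data$gene_distance)) +
    geom_density(fill = "grey80", colour = "grey40") +
    geom_vline(xintercept = object$te_distance, colour = "red",
               linewidth = 1) +
    labs(x = "K2P distance", y = "Density",
         title = sprintf("Element vs %d host orthologs (call: %s)",
                         object$n_genes, object$call)) +
    theme_minimal()
}

#' Write an HT test result as JSON
#'
#' @param x An `ht_test`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ht_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' K2P distances for a set of ortholog pairs
#'
#' Globally aligns each ortholog pair and returns the K2P distance per
#' gene.
#'
#' @param orthologs Tibble with `gene_id`, `seq_a`, `seq_b` columns (as
#'   produced by [simulate_ht_scenario()] or read from paired FASTA files).
#' @param ... Scoring parameters passed to [pairwise_align()].
#' @return Tibble with `gene_id`, `k`, `P`, `Q`, `n_sites`, `status`.
#' @export
ortholog_distances <- function(orthologs, ...) {
  purrr::map_dfr(seq_len(nrow(orthologs)), function(i) {
    res <- k2p_aligned_pair(orthologs$seq_a[i], orthologs$seq_b[i],
                            mode = "global", ...)
    res$gene_id <- orthologs$gene_id[i]
    dplyr::relocate(res, "gene_id")
  })
}

#' Read ortholog pairs from two FASTA files
#'
#' Sequences are paired by shared identifier; identifiers present in only
#' one file are dropped with a warning.
#'
#' @param path_a,path_b FASTA files for the two species.
#' @return Tibble with `gene_id`, `seq_a`, `seq_b`.
#' @export
read_ortholog_pairs <- function(path_a, path_b) {
  a <- read_fasta(path_a)
  b <- read_fasta(path_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) < length(a) || length(shared) < length(b)) {
    warn("dropping unpaired ortholog identifiers")
  }
  tibble(gene_id = shared, seq_a = unname(a[shared]),
         seq_b = unname(b[shared]))
}
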