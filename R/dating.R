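#' Avian substitution-rate table
#'
#' Species-specific (or closest-relative) neutral substitution rates in
#' substitutions/site/My used for element dating, plus the low water-bird
#' rate used for sensitivity re-dating.
#'
#' @return Tibble with `species_id` and `rate`.
#' @export
avian_rate_table <- function() {
  tibble(
    species_id = c("G_gallus", "M_gallopavo", "B_rhinoceros", "L_tetrix",
                   "C_virginianus", "water_bird"),
    rate = c(1.9e-3, 2.0e-3, 2.3e-3, 1.9e-3, 1.9e-3, 1.6e-3)
  )
}

#' Copy age from K2P divergence
#'
#' `T = k / (2 r)`: a copy and the consensus it is compared with have each
#' accumulated `r T` substitutions per site since the copy inserted, so
#' their divergence grows at `2 r`.
#'
#' @param k K2P divergence(s), >= 0 (NA propagates).
#' @param r Substitution rate in substitutions/site/My (> 0).
#' @return Ages in My.
#' @export
#' @examples
#' age_from_divergence(0.1, 1.9e-3)  # 26.32 My
age_from_divergence <- function(k, r) {
  if (length(r) != 1 || r <= 0) abort("rate must be a single positive value")
  if (any(k < 0, na.rm = TRUE)) abort("divergence must be >= 0")
  k / (2 * r)
}

#' Re-date ages under a different substitution rate
#'
#' Multiplies each age by `r_old / r_new`, equivalent to re-applying
#' `T = k / (2 r)` to the same divergences at the new rate.
#'
#' @param ages Ages in My.
#' @param r_old,r_new Old and new rates (> 0).
#' @return Rescaled ages.
#' @export
rescale_ages <- function(ages, r_old, r_new) {
  if (r_old <= 0 || r_new <= 0) abort("rates must be > 0")
  ages * (r_old / r_new)
}

#' Age histogram with amplification-wave peaks
#'
#' Bins copy ages over `[0, max(age)]` and locates amplification waves as
#' strict local maxima of the histogram; runs of adjacent equal-count
#' maximal bins are merged into a single plateau peak; peaks must hold at
#' least `peak_min_fraction` of all dated copies. The default bin width of
#' 6.25 My places the reference wave endpoints (18.75, 37.5, 87.5 My) on
#' bin edges.
#'
#' @param ages Numeric vector of copy ages in My (NA entries dropped with a
#'   warning; at least one age required).
#' @param bin_width Bin width in My (default 6.25).
#' @param peak_min_fraction Minimum fraction of all copies a peak bin must
#'   contain (default 0.05).
#' @param species_id Optional label.
#' @return An `age_distribution`: list with `species_id`, `ages`,
#'   `bin_width`, `bins` (tibble: `bin_start`, `bin_end`, `count`,
#'   `is_peak`) and `peaks` (tibble: `peak_start`, `peak_end`, `mid`,
#'   `count`).
#' @export
age_histogram_peaks <- function(ages, bin_width = 6.25,
                                peak_min_fraction = 0.05,
                                species_id = NA_character_) {
  if (any(is.na(ages))) {
    warn("dropping NA ages (saturated copies)")
    ages <- ages[!is.na(ages)]
  }
  if (length(ages) == 0) abort("need at least one age")
  if (any(ages < 0)) abort("ages must be >= 0")
  n_bins <- max(1L, ceiling(max(ages) / bin_width))
  if (max(ages) == n_bins * bin_width && max(ages) > 0) n_bins <- n_bins  # right edge closed below
  bin <- pmin(floor(ages / bin_width) + 1L, n_bins)   # last bin closed on the right
  counts <- tabulate(bin, nbins = n_bins)
  total <- length(ages)

  r <- rle(counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  is_peak_run <- vapply(seq_along(r$values), function(i) {
    v <- r$values[i]
    left_ok <- i == 1 || v > r$values[i - 1]
    right_ok <- i == length(r$values) || v > r$values[i + 1]
    v > 0 && left_ok && right_ok && v >= peak_min_fraction * total
  }, logical(1))
  is_peak <- rep(FALSE, n_bins)
  for (i in which(is_peak_run)) is_peak[starts[i]:ends[i]] <- TRUE

  bins <- tibble(
    bin_start = bin_width * (seq_len(n_bins) - 1),
    bin_end = bin_width * seq_len(n_bins),
    count = counts,
    is_peak = is_peak
  )
  peaks <- purrr::map_dfr(which(is_peak_run), function(i) {
    tibble(peak_start = bin_width * (starts[i] - 1),
           peak_end = bin_width * ends[i],
           mid = bin_width * (starts[i] - 1 + ends[i]) / 2,
           count = sum(counts[starts[i]:ends[i]]))
  })
  structure(
    list(species_id = species_id, ages = ages, bin_width = bin_width,
         bins = bins, peaks = peaks),
    class = "age_distribution"
  )
}

#' @export
print.age_distribution <- function(x, ...) {
  cat(sprintf("<age_distribution%s: %d copies, %d bins of %.3g My, %d peak(s)%s>\n",
              if (is.na(x$species_id)) "" else paste0(" ", x$species_id),
              length(x$ages), nrow(x$bins), x$bin_width, nrow(x$peaks),
              if (nrow(x$peaks)) paste0(" at ",
                paste(sprintf("%.3g", x$peaks$mid), collapse = ", "), " My")
              else ""))
  invisible(x)
}

#' @export
tidy.age_distribution <- function(x, ...) x$bins

#' @export
glance.age_distribution <- function(x, ...) {
  tibble(species_id = x$species_id, n_copies = length(x$ages),
         mean_age = mean(x$ages), bin_width = x$bin_width,
         n_peaks = nrow(x$peaks))
}

#' @export
autoplot.age_distribution <- function(object, ...) {
  bins <- object$bins
  ggplot(bins, aes(x = (.data$bin_start + .data$bin_end) / 2,
                   y = .data$count, fill = .data$is_peak)) +
    geom_col(width = object$bin_width, colour = "grey30", linewidth = 0.2) +
    labs(x = "Copy age (My)", y = "Copies",
         title = object$species_id, fill = "Peak bin") +
    theme_minimal()
}

#' Write a per-copy age table as TSV
#'
#' @param divergences Tibble from [divergence_table()] with an `age_My`
#'   column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_age_tsv <- function(divergences, path) {
  out <- divergences
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, 4)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
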