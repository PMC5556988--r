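#' Pipeline configuration
#'
#' Bundles inputs and per-stage parameters for [run_pipeline()]. Species
#' identity is taken from the names of `genomes`, never inferred from
#' sequence content.
#'
#' @param genomes Named list/vector: species id -> genome (FASTA path,
#'   named character vector or DNAStringSet).
#' @param query Query element consensus (FASTA path or string).
#' @param output_dir Output directory (created if missing).
#' @param seed RNG seed recorded and set at the start of the run.
#' @param rates Named numeric vector of substitution rates per species;
#'   species missing from it fall back to `default_rate`.
#' @param default_rate Fallback substitution rate (substitutions/site/My).
#' @param word_size,e_max,x_drop Mining parameters, see [te_search()].
#' @param max_gap HSP merge distance, see [merge_hits()].
#' @param flank Flank length for copy extraction.
#' @param min_tir_len,max_tir_len,min_tir_identity,tir_window,min_orf_aa
#'   Annotation thresholds, see [annotate_copies()].
#' @param min_coverage Consensus column coverage threshold.
#' @param bin_width,peak_min_fraction Age histogram parameters.
#' @param ht_threshold,ht_lower HT-test decision thresholds.
#' @param orthologs Optional list of ortholog sets for HT testing, each a
#'   list with `species_a`, `species_b`, and either `pairs` (tibble of
#'   gene_id/seq_a/seq_b) or `path_a`/`path_b` FASTA files.
#' @param verbose Log stage-level progress to the console as well as the
#'   run log.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genomes, query, output_dir, seed = 1,
                            rates = NULL, default_rate = 1.9e-3,
                            word_size = 11, e_max = 1e-10, x_drop = 40,
                            max_gap = 100, flank = 200, min_tir_len = 20,
                            max_tir_len = 40, min_tir_identity = 0.8,
                            tir_window = 60, min_orf_aa = 300,
                            min_coverage = 0.2, bin_width = 6.25,
                            peak_min_fraction = 0.05, ht_threshold = 0.9,
                            ht_lower = 0.25, orthologs = NULL,
                            verbose = FALSE) {
  if (is.null(names(genomes)) || any(!nzchar(names(genomes)))) {
    abort("genomes must be named by species id")
  }
  structure(
    list(genomes = as.list(genomes), query = query, output_dir = output_dir,
         seed = seed, rates = rates, default_rate = default_rate,
         word_size = word_size, e_max = e_max, x_drop = x_drop,
         max_gap = max_gap, flank = flank, min_tir_len = min_tir_len,
         max_tir_len = max_tir_len, min_tir_identity = min_tir_identity,
         tir_window = tir_window, min_orf_aa = min_orf_aa,
         min_coverage = min_coverage, bin_width = bin_width,
         peak_min_fraction = peak_min_fraction, ht_threshold = ht_threshold,
         ht_lower = ht_lower, orthologs = orthologs, verbose = verbose),
    class = "pipeline_config"
  )
}

#' Summarise a species' copy set
#'
#' Aggregates per-copy annotations into the per-species report row:
#' functional class counts, size class counts, the MITE fraction
#' (non-autonomous copies over all copies), a divergence summary and age
#' peaks.
#'
#' @param species_id Species label.
#' @param annotations Tibble from [annotate_copies()].
#' @param divergences Optional tibble from [divergence_table()]; must cover
#'   exactly the same copy ids.
#' @param age_dist Optional `age_distribution`.
#' @param consensus_length Optional consensus length in bp.
#' @return A `species_report` list.
#' @export
summarize_species <- function(species_id, annotations, divergences = NULL,
                              age_dist = NULL, consensus_length = NA_integer_) {
  classes <- c("potential_autonomous", "potential_non_autonomous",
               "potential_coding", "partial")
  n <- nrow(annotations)
  class_counts <- vapply(classes, function(cl) {
    sum(annotations$functional_class == cl)
  }, integer(1))
  if (sum(class_counts) != n) {
    abort("class counts do not sum to the number of copies")
  }
  size_classes <- c("full_length", "mite", "partial_size")
  size_counts <- vapply(size_classes, function(cl) {
    sum(annotations$size_class == cl)
  }, integer(1))
  if (!is.null(divergences)) {
    if (!setequal(divergences$copy_id, annotations$copy_id)) {
      abort("divergence table and annotations cover different copies")
    }
  }
  mite_fraction <- if (n > 0) class_counts[["potential_non_autonomous"]] / n else 0
  structure(
    list(
      species_id = species_id,
      n_copies = n,
      class_counts = as.list(class_counts),
      size_counts = as.list(size_counts),
      mite_fraction = mite_fraction,
      mite_fraction_pct = round(100 * mite_fraction, 1),
      n_with_tsd = sum(!is.na(annotations$tsd)),
      consensus_length = consensus_length,
      divergence = if (!is.null(divergences)) {
        ok <- divergences$k[divergences$status == "ok"]
        list(n_ok = length(ok), n_saturated = sum(divergences$status != "ok"),
             mean_k = if (length(ok)) mean(ok) else NA_real_,
             median_k = if (length(ok)) stats::median(ok) else NA_real_)
      },
      age_peaks = if (!is.null(age_dist)) {
        lapply(seq_len(nrow(age_dist$peaks)), function(i) {
          as.list(age_dist$peaks[i, ])
        })
      }
    ),
    class = "species_report"
  )
}

#' @export
print.species_report <- function(x, ...) {
  cat(sprintf("<species_report %s: %d copies, MITE fraction %.1f%%>\n",
              x$species_id, x$n_copies, x$mite_fraction_pct))
  invisible(x)
}

#' @export
glance.species_report <- function(x, ...) {
  tibble(species_id = x$species_id, n_copies = x$n_copies,
         n_non_autonomous = x$class_counts$potential_non_autonomous,
         n_partial = x$class_counts$partial,
         mite_fraction_pct = x$mite_fraction_pct,
         consensus_length = x$consensus_length)
}

#' MITE fraction from printed class counts
#'
#' Convenience constructor for report rows known only through their class
#' counts (e.g. transcribed from a publication table). Errors when the
#' counts do not sum to the stated total.
#'
#' @param partial,non_autonomous,full_length,coding Copy counts per class.
#' @param total Stated total copy count.
#' @return Tibble with the counts, `mite_fraction` and `mite_fraction_pct`
#'   (rounded to 0.1%).
#' @export
#' @examples
#' class_count_summary(0, 8187, 130, total = 8317)
class_count_summary <- function(partial, non_autonomous, full_length,
                                coding = 0, total) {
  if (partial + non_autonomous + full_length + coding != total) {
    abort("class counts do not sum to the stated total")
  }
  frac <- if (total > 0) non_autonomous / total else 0
  tibble(partial = partial, non_autonomous = non_autonomous,
         full_length = full_length, coding = coding, total = total,
         mite_fraction = frac, mite_fraction_pct = round(100 * frac, 1))
}

#' Run the full mine-annotate-date-test pipeline
#'
#' For every genome: seed-and-extend mining, HSP merging, copy extraction,
#' structural annotation, majority consensus against the query, per-copy
#' K2P divergence, dating and age-histogram peaks. Across species:
#' consensus distance matrix, neighbor-joining tree (3+ species) and
#' HT quantile tests for every configured ortholog set. All artifacts are
#' written under `output_dir`; the machine-readable surface is
#' `report.json` (identical config and seed reproduce it byte for byte).
#' A genome with zero hits yields an empty but valid report entry.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the report list (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  log_path <- file.path(config$output_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    line <- sprintf(...)
    writeLines(line, log_con)
    if (isTRUE(config$verbose)) message(line)
  }
  logmsg("tepaleo %s | seed %d", as.character(utils::packageVersion("tepaleo")),
         config$seed)
  logmsg("params: word_size=%d e_max=%g max_gap=%d flank=%d min_orf_aa=%d",
         config$word_size, config$e_max, config$max_gap, config$flank,
         config$min_orf_aa)

  query <- as_single_seq(config$query, "query")
  species_reports <- list()
  profiles <- list()
  copies_by_species <- list()

  for (sp in names(config$genomes)) {
    genome <- as_genome_chars(config$genomes[[sp]])
    logmsg("[%s] genome: %d contig(s), %d bp", sp, length(genome),
           sum(nchar(genome)))
    hsps <- te_search(genome, query, word_size = config$word_size,
                      x_drop = config$x_drop, e_max = config$e_max)
    logmsg("[%s] mining: %d HSPs at E <= %g", sp, nrow(hsps), config$e_max)
    loci <- merge_hits(hsps, max_gap = config$max_gap)
    copies <- extract_copies(genome, loci, flank = config$flank)
    copies$copy_id <- paste0(sp, "_", copies$copy_id)
    logmsg("[%s] %d loci -> %d copies", sp, nrow(loci), nrow(copies))
    write_hits_tsv(hsps, file.path(config$output_dir, paste0(sp, "_hits.tsv")))
    write_hits_bed(loci, file.path(config$output_dir, paste0(sp, "_loci.bed")))

    if (nrow(copies) == 0) {
      species_reports[[sp]] <- summarize_species(sp, annotate_copies(copies))
      logmsg("[%s] no copies found; empty report", sp)
      next
    }
    write_copies_fasta(copies, file.path(config$output_dir,
                                         paste0(sp, "_copies.fasta")))
    ann <- annotate_copies(copies, min_tir_len = config$min_tir_len,
                           max_tir_len = config$max_tir_len,
                           min_tir_identity = config$min_tir_identity,
                           tir_window = config$tir_window,
                           min_orf_aa = config$min_orf_aa)
    write_annotation_tsv(ann, file.path(config$output_dir,
                                        paste0(sp, "_annotations.tsv")))
    logmsg("[%s] annotation: %d with TIRs, %d with TSD", sp,
           sum(ann$tir_found), sum(!is.na(ann$tsd)))

    profile <- build_majority_consensus(copies, query,
                                        min_coverage = config$min_coverage,
                                        species_id = sp)
    profiles[[sp]] <- profile
    write_consensus_fasta(profile, file.path(config$output_dir,
                                             paste0(sp, "_consensus.fasta")))
    rate <- if (!is.null(config$rates) && sp %in% names(config$rates)) {
      config$rates[[sp]]
    } else {
      config$default_rate
    }
    div <- divergence_table(copies, profile, rate = rate)
    write_age_tsv(div, file.path(config$output_dir, paste0(sp, "_ages.tsv")))
    ok_ages <- div$age_My[div$status == "ok"]
    age_dist <- if (length(ok_ages)) {
      age_histogram_peaks(ok_ages, bin_width = config$bin_width,
                          peak_min_fraction = config$peak_min_fraction,
                          species_id = sp)
    }
    logmsg("[%s] consensus %d bp; %d dated copies; %d age peak(s)", sp,
           nchar(profile$consensus), length(ok_ages),
           if (is.null(age_dist)) 0L else nrow(age_dist$peaks))
    species_reports[[sp]] <- summarize_species(
      sp, ann, div, age_dist, consensus_length = nchar(profile$consensus))
    copies_by_species[[sp]] <- copies
  }

  dist_matrix <- NULL
  if (length(profiles) >= 2) {
    dist_matrix <- consensus_distance_matrix(profiles)
    write_distance_tsv(dist_matrix,
                       file.path(config$output_dir, "consensus_k2p.tsv"))
    if (length(profiles) >= 3 && !any(is.na(dist_matrix))) {
      writeLines(nj_tree(dist_matrix),
                 file.path(config$output_dir, "consensus_nj.nwk"))
    }
  }

  ht_results <- list()
  for (set in config$orthologs %||% list()) {
    pa <- set$species_a; pb <- set$species_b
    pairs <- if (!is.null(set$pairs)) set$pairs
             else read_ortholog_pairs(set$path_a, set$path_b)
    if (is.null(profiles[[pa]]) || is.null(profiles[[pb]])) {
      logmsg("[httest %s-%s] skipped: missing consensus", pa, pb)
      next
    }
    te_k <- k2p_aligned_pair(profiles[[pa]]$consensus,
                             profiles[[pb]]$consensus)$k
    gene_k <- ortholog_distances(pairs)
    usable <- gene_k$k[gene_k$status == "ok"]
    ht <- ht_quantile_test(te_k, usable, threshold = config$ht_threshold,
                           lower = config$ht_lower)
    key <- paste0(pa, "-", pb)
    ht_results[[key]] <- ht
    write_ht_json(ht, file.path(config$output_dir,
                                paste0("ht_", pa, "_", pb, ".json")))
    logmsg("[httest %s] TE k=%.4f, %d/%d genes greater, call=%s", key,
           te_k, ht$n_genes_greater, ht$n_genes, ht$call)
  }

  report <- list(
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("genomes", "query", "orthologs", "verbose",
                                  "output_dir"))],
    species = lapply(species_reports, unclass),
    consensus_distances = if (!is.null(dist_matrix)) {
      list(labels = rownames(dist_matrix),
           matrix = unname(apply(dist_matrix, 1, as.list)))
    },
    ht_tests = lapply(ht_results, function(h) {
      unclass(h)[c("te_distance", "n_genes", "n_genes_greater",
                   "fraction_greater", "threshold", "call")]
    })
  )
  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  logmsg("report written")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a flat key=value pipeline configuration file
#'
#' Recognised keys mirror [pipeline_config()] arguments; genomes are given
#' as `genome.<species> = <fasta>`, per-species rates as
#' `rate.<species> = <value>`, and ortholog sets as
#' `ortholog_a.<pair> = <fasta>`, `ortholog_b.<pair> = <fasta>`,
#' `ortholog_species.<pair> = <speciesA>,<speciesB>`.
#'
#' @param path Config file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  if (any(lengths(kv) != 2)) abort("malformed config line")
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- lapply(kv, function(p) utils::type.convert(p[2], as.is = TRUE))
  names(vals) <- keys

  pick <- function(prefix) {
    sel <- startsWith(keys, paste0(prefix, "."))
    setNames(vals[sel], sub(paste0("^", prefix, "\\."), "", keys[sel]))
  }
  genomes <- pick("genome")
  if (length(genomes) == 0) abort("config must define at least one genome.<species>")
  rates <- unlist(pick("rate"))
  oa <- pick("ortholog_a"); ob <- pick("ortholog_b"); osp <- pick("ortholog_species")
  orthologs <- lapply(names(oa), function(pair) {
    spp <- strsplit(as.character(osp[[pair]]), ",")[[1]]
    list(species_a = trimws(spp[1]), species_b = trimws(spp[2]),
         path_a = oa[[pair]], path_b = ob[[pair]])
  })
  scalar_keys <- intersect(names(vals), names(formals(pipeline_config)))
  args <- vals[scalar_keys]
  args$genomes <- genomes
  args$rates <- if (length(rates)) rates
  args$orthologs <- if (length(orthologs)) orthologs
  do.call(pipeline_config, args)
}
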