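#' Pipeline configuration
#'
#' @param male_r1,male_r2,female_r1,female_r2 FASTQ paths (optionally
#'   gzipped) for the two sequenced individuals.
#' @param out_dir Output directory for intermediates and the manifest.
#' @param k K-mer size (odd, default 27).
#' @param male_threshold,female_threshold Error thresholds; `NULL` (the
#'   default) auto-detects each from its k-mer spectrum valley, falling
#'   back to 1 (no filtering) with a manifest note when the spectrum has
#'   no valley (e.g. error-free input).
#' @param min_overlap,max_mismatch_frac Pair-merging parameters, see
#'   [merge_pairs()].
#' @param min_contig_length,top_n Contig selection, see
#'   [filter_and_rank()].
#' @param smooth_spectrum Median-smooth spectra before valley detection.
#' @param seed_order,rng_seed Assembly determinism, see [assemble()].
#' @param id_prefix Contig id prefix.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(male_r1, male_r2, female_r1, female_r2,
                            out_dir, k = 27L,
                            male_threshold = NULL, female_threshold = NULL,
                            min_overlap = 10L, max_mismatch_frac = 0.1,
                            min_contig_length = 80L, top_n = 92L,
                            smooth_spectrum = FALSE,
                            seed_order = "sorted", rng_seed = 1L,
                            id_prefix = "ksub") {
  stopifnot(k >= 3L, k %% 2L == 1L, top_n >= 1L)
  structure(list(male_r1 = male_r1, male_r2 = male_r2,
                 female_r1 = female_r1, female_r2 = female_r2,
                 out_dir = out_dir, k = as.integer(k),
                 male_threshold = male_threshold,
                 female_threshold = female_threshold,
                 min_overlap = as.integer(min_overlap),
                 max_mismatch_frac = max_mismatch_frac,
                 min_contig_length = as.integer(min_contig_length),
                 top_n = top_n, smooth_spectrum = smooth_spectrum,
                 seed_order = seed_order, rng_seed = as.integer(rng_seed),
                 id_prefix = id_prefix),
            class = "pipeline_config")
}

.count_sex <- function(config, sex, force) {
  paths <- list(r1 = config[[paste0(sex, "_r1")]],
                r2 = config[[paste0(sex, "_r2")]])
  tab_path <- file.path(config$out_dir, paste0(sex, "_kmers.tsv.gz"))
  if (file.exists(tab_path) && !force) {
    tab <- read_kmer_table(tab_path)
    return(list(table = tab, n_pairs = NA_integer_,
                n_merged = NA_integer_, from_cache = TRUE))
  }
  pairs <- read_fastq_pairs(paths$r1, paths$r2)
  frags <- merge_pairs(pairs$r1, pairs$r2,
                       min_overlap = config$min_overlap,
                       max_mismatch_frac = config$max_mismatch_frac)
  tab <- count_kmers(frags$seq, k = config$k)
  write_kmer_table(tab, tab_path)
  list(table = tab, n_pairs = nrow(pairs$r1),
       n_merged = sum(frags$source == "merged"), from_cache = FALSE)
}

.threshold_sex <- function(table, override, smooth) {
  spec <- build_spectrum(table)
  if (!is.null(override)) {
    return(list(t = as.integer(override), spectrum = spec,
                auto = FALSE, fallback = FALSE))
  }
  t <- tryCatch(find_error_threshold(spec, smooth = smooth),
                ksub_no_valley_error = function(e) NA_integer_)
  if (is.na(t)) {
    warning("no spectrum valley found; retaining all k-mers (t = 1)",
            call. = FALSE)
    list(t = 1L, spectrum = spec, auto = TRUE, fallback = TRUE)
  } else {
    list(t = t, spectrum = spec, auto = TRUE, fallback = FALSE)
  }
}

#' Run the whole-genome subtraction pipeline
#'
#' Executes merge -> count -> spectrum/threshold -> filter -> subtract ->
#' assemble -> select, persisting intermediates (per-sex k-mer tables and
#' spectra, the male-unique table, contig FASTA) and a JSON manifest of
#' stage tallies under `config$out_dir`. Re-runs reuse existing per-sex
#' k-mer tables unless `force = TRUE`.
#'
#' @param config A [pipeline_config()].
#' @param force Recompute stages whose outputs already exist.
#' @return The manifest, invisibly a list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  male <- .count_sex(config, "male", force)
  female <- .count_sex(config, "female", force)

  thr_m <- .threshold_sex(male$table, config$male_threshold,
                          config$smooth_spectrum)
  thr_f <- .threshold_sex(female$table, config$female_threshold,
                          config$smooth_spectrum)
  write_spectrum <- function(spec, sex) {
    data.table::fwrite(spec$histogram,
                       file.path(config$out_dir,
                                 paste0(sex, "_spectrum.tsv")),
                       sep = "\t")
  }
  write_spectrum(thr_m$spectrum, "male")
  write_spectrum(thr_f$spectrum, "female")

  male_f <- filter_by_count(male$table, thr_m$t)
  female_f <- filter_by_count(female$table, thr_f$t)

  sub <- subtract_kmers(male_f, female_f)
  write_kmer_table(sub$unique,
                   file.path(config$out_dir, "male_unique.tsv.gz"))

  contigs <- assemble(sub$unique, seed_order = config$seed_order,
                      rng_seed = config$rng_seed,
                      id_prefix = config$id_prefix)
  selected <- filter_and_rank(contigs,
                              min_length = config$min_contig_length,
                              top_n = config$top_n)
  write_contigs(contigs, file.path(config$out_dir, "contigs_all.fa"))
  write_contigs(selected, file.path(config$out_dir, "contigs_selected.fa"))

  manifest <- list(
    parameters = list(
      k = config$k, min_overlap = config$min_overlap,
      max_mismatch_frac = config$max_mismatch_frac,
      min_contig_length = config$min_contig_length,
      top_n = config$top_n, seed_order = config$seed_order,
      rng_seed = config$rng_seed),
    male = list(
      n_read_pairs = male$n_pairs, n_merged_pairs = male$n_merged,
      total_kmer_instances = sum(as.numeric(male$table$counts$count)),
      distinct_kmers = nrow(male$table$counts),
      n_skipped_windows = male$table$n_skipped,
      threshold = thr_m$t, threshold_auto = thr_m$auto,
      threshold_fallback = thr_m$fallback,
      retained_kmers = nrow(male_f$counts)),
    female = list(
      n_read_pairs = female$n_pairs, n_merged_pairs = female$n_merged,
      total_kmer_instances = sum(as.numeric(female$table$counts$count)),
      distinct_kmers = nrow(female$table$counts),
      n_skipped_windows = female$table$n_skipped,
      threshold = thr_f$t, threshold_auto = thr_f$auto,
      threshold_fallback = thr_f$fallback,
      retained_kmers = nrow(female_f$counts)),
    subtraction = unclass(sub$summary),
    assembly = list(
      n_contigs = nrow(contigs),
      n_selected = nrow(selected),
      contig_length_min = if (nrow(contigs)) min(contigs$length) else NA,
      contig_length_max = if (nrow(contigs)) max(contigs$length) else NA,
      selected_length_min = if (nrow(selected)) min(selected$length) else NA,
      selected_length_max = if (nrow(selected)) max(selected$length) else NA))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(manifest)
}
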