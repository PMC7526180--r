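#' Simulation parameters for a synthetic XX/XY study
#'
#' The defaults describe the desk-scale scenario used throughout the test
#' suite: a 100 kb shared background, three Y-specific insertions of
#' 200/500/2000 bp, male heterozygosity 1e-3, a 2 kb X/Y gametolog region
#' diverged at 2%, 150 bp paired-end reads at 8-fold base coverage with
#' 0.5% substitution error and 220 +/- 40 bp fragments.
#'
#' @param genome_length Shared (female) genome length, bp.
#' @param y_insertion_lengths Lengths of the Y-specific insertions, bp.
#' @param heterozygosity Per-base substitution rate applied to the male
#'   copy of the shared sequence: emulates presence/absence-style
#'   polymorphism between the two sequenced individuals, the main source
#'   of autosomal false positives.
#' @param x_gametolog_divergence Per-base substitution rate applied to the
#'   male copy of one designated region, emulating a diverged Y gametolog
#'   of X sequence.
#' @param gametolog_region_length Length of that region, bp (0 disables).
#' @param read_length Read length, bp.
#' @param fragment_mean,fragment_sd Library fragment length distribution,
#'   bp (normal, truncated at `read_length`).
#' @param coverage Expected sequenced base coverage (reads x length /
#'   genome length).
#' @param error_rate Per-base substitution error rate of the reads.
#' @param rng_seed Integer seed; everything downstream is deterministic in
#'   it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(genome_length = 100000L,
                       y_insertion_lengths = c(200L, 500L, 2000L),
                       heterozygosity = 1e-3,
                       x_gametolog_divergence = 0.02,
                       gametolog_region_length = 2000L,
                       read_length = 150L,
                       fragment_mean = 220,
                       fragment_sd = 40,
                       coverage = 8,
                       error_rate = 0.005,
                       rng_seed = 1L) {
  p <- list(genome_length = as.integer(genome_length),
            y_insertion_lengths = as.integer(y_insertion_lengths),
            heterozygosity = heterozygosity,
            x_gametolog_divergence = x_gametolog_divergence,
            gametolog_region_length = as.integer(gametolog_region_length),
            read_length = as.integer(read_length),
            fragment_mean = fragment_mean,
            fragment_sd = fragment_sd,
            coverage = coverage,
            error_rate = error_rate,
            rng_seed = as.integer(rng_seed))
  stopifnot(p$genome_length > 0,
            all(p$y_insertion_lengths >= 1L) ||
              length(p$y_insertion_lengths) == 0L,
            sum(p$y_insertion_lengths) < p$genome_length,
            p$heterozygosity >= 0, p$heterozygosity <= 1,
            p$x_gametolog_divergence >= 0, p$x_gametolog_divergence <= 1,
            p$read_length > 0, p$fragment_mean >= p$read_length,
            p$fragment_sd >= 0, p$coverage > 0,
            p$error_rate >= 0, p$error_rate <= 1)
  structure(p, class = "sim_params")
}

.BASES <- c("A", "C", "G", "T")

.random_dna <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# substitute positions `pos` of character vector `v` with a different base
.substitute_bases <- function(v, pos) {
  if (length(pos) == 0L) return(v)
  old <- v[pos]
  shift <- sample.int(3L, length(pos), replace = TRUE)
  v[pos] <- .BASES[(match(old, .BASES) - 1L + shift) %% 4L + 1L]
  v
}

#' Simulate an XX/XY genome pair with known Y-specific truth
#'
#' The female genome is uniform random sequence. The male genome is a copy
#' with (i) each Y insertion of novel random sequence implanted at a random
#' position (insertion points pairwise at least one insertion apart), (ii)
#' the male copy of a designated gametolog region substituted at
#' `x_gametolog_divergence`, and (iii) independent heterozygous
#' substitutions at rate `heterozygosity` over the shared (non-insertion)
#' male sequence. Truth intervals record the insertions exactly, in
#' 0-based half-open male-genome coordinates.
#'
#' @param params A [sim_params()] object.
#' @return A `genome_pair`: list with `female_genome`, `male_genome`
#'   (single sequences), `y_intervals` (data.frame `contig`, `start`,
#'   `end`), `gametolog_interval` and `n_het_sites`.
#' @export
simulate_genome_pair <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$rng_seed, {
    G <- params$genome_length
    female_chars <- sample(.BASES, G, replace = TRUE)
    ins_lens <- params$y_insertion_lengths
    n_ins <- length(ins_lens)

    # insertion points in female coordinates (after base i, 0..G); retried
    # until pairwise distinct with >= 1 bp of shared sequence between them
    points <- integer(0)
    if (n_ins > 0L) {
      for (attempt in seq_len(100L)) {
        points <- sort(sample.int(G - 1L, n_ins))
        if (n_ins == 1L || min(diff(points)) >= 1L) break
        if (attempt == 100L) {
          stop("could not place non-overlapping insertions", call. = FALSE)
        }
      }
    }
    # junction-distinct insertions: the first inserted base must differ
    # from the shared base that follows the insertion point and the last
    # from the shared base that precedes it, otherwise the insertion is
    # shift-ambiguous and the truth interval would not exactly delimit the
    # sequence absent from the female genome
    ins_seqs <- lapply(seq_len(n_ins), function(i) {
      L <- ins_lens[i]
      s <- sample(.BASES, L, replace = TRUE)
      before <- female_chars[points[i]]
      after <- female_chars[points[i] + 1L]
      if (L == 1L) {
        s[1L] <- sample(setdiff(.BASES, c(before, after)), 1L)
      } else {
        if (s[1L] == after) s[1L] <- sample(setdiff(.BASES, after), 1L)
        if (s[L] == before) s[L] <- sample(setdiff(.BASES, before), 1L)
      }
      s
    })

    # assemble male as alternating shared/insert blocks, tracking male
    # coordinates of each insertion
    male_blocks <- list()
    y_start <- integer(n_ins)
    y_end <- integer(n_ins)
    prev <- 0L
    offset <- 0L
    for (i in seq_len(n_ins)) {
      shared <- female_chars[seq_len(points[i] - prev) + prev]
      male_blocks[[length(male_blocks) + 1L]] <- shared
      y_start[i] <- points[i] + offset
      y_end[i] <- y_start[i] + ins_lens[i]
      male_blocks[[length(male_blocks) + 1L]] <- ins_seqs[[i]]
      offset <- offset + ins_lens[i]
      prev <- points[i]
    }
    male_blocks[[length(male_blocks) + 1L]] <-
      female_chars[seq_len(G - prev) + prev]
    male_chars <- unlist(male_blocks, use.names = FALSE)

    # male positions belonging to shared (non-insertion) sequence
    is_shared <- rep(TRUE, length(male_chars))
    for (i in seq_len(n_ins)) {
      is_shared[(y_start[i] + 1L):y_end[i]] <- FALSE
    }
    shared_pos <- which(is_shared)

    # gametolog region: a run of shared positions substituted at the
    # divergence rate on the male copy
    gam <- NULL
    Lg <- params$gametolog_region_length
    if (Lg > 0L && params$x_gametolog_divergence > 0) {
      # pick a shared run of length Lg in female coordinates, away from
      # insertion points so the region is contiguous in the male too
      gaps <- cbind(c(0L, points), c(points, G))
      widths <- gaps[, 2L] - gaps[, 1L]
      ok <- which(widths >= Lg + 2L)
      if (length(ok) == 0L) {
        stop("no shared run long enough for the gametolog region",
             call. = FALSE)
      }
      gi <- ok[which.max(widths[ok])]
      f_start <- gaps[gi, 1L] + sample.int(widths[gi] - Lg - 1L, 1L)
      # male coordinate of that female position
      m_start <- f_start + sum(ins_lens[points <= f_start])
      region <- (m_start + 1L):(m_start + Lg)
      hit <- region[stats::runif(Lg) < params$x_gametolog_divergence]
      male_chars <- .substitute_bases(male_chars, hit)
      gam <- data.frame(contig = "male", start = m_start,
                        end = m_start + Lg)
    }

    # heterozygous substitutions on the male copy of shared sequence
    het_pos <- shared_pos[stats::runif(length(shared_pos)) <
                            params$heterozygosity]
    if (!is.null(gam)) {
      het_pos <- setdiff(het_pos, (gam$start + 1L):gam$end)
    }
    male_chars <- .substitute_bases(male_chars, het_pos)

    structure(list(
      female_genome = c(female = paste(female_chars, collapse = "")),
      male_genome = c(male = paste(male_chars, collapse = "")),
      y_intervals = data.frame(contig = rep("male", n_ins),
                               start = y_start, end = y_end,
                               stringsAsFactors = FALSE),
      gametolog_interval = gam,
      n_het_sites = length(het_pos),
      params = params), class = "genome_pair")
  })
}

#' Write the truth intervals of a simulated pair as BED
#'
#' @param pair A `genome_pair`.
#' @param path Output path (3-column BED, 0-based half-open).
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(pair, path) {
  utils::write.table(pair$y_intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate paired-end reads from a genome
#'
#' Fragments are drawn uniformly along the genome with normal length
#' (truncated at the read length), from either strand with equal
#' probability; read 1 is the fragment 5' prefix and read 2 the reverse
#' complement of its 3' suffix. Substitution errors are applied
#' independently per base at `error_rate`; qualities are constant Phred
#' 40. The number of pairs is chosen so the expected sequenced base
#' coverage equals `coverage`.
#'
#' @param genome Single DNA sequence (character scalar).
#' @param params A [sim_params()] object; `read_length`, `fragment_mean`,
#'   `fragment_sd`, `coverage` and `error_rate` are used.
#' @param rng_seed Seed for this read set (defaults to the one in
#'   `params`).
#' @param id_prefix Read id prefix.
#' @return List with `r1` and `r2` data.frames (`id`, `seq`, `qual`).
#' @export
simulate_reads <- function(genome, params = sim_params(),
                           rng_seed = params$rng_seed,
                           id_prefix = "sim") {
  stopifnot(is.character(genome), length(genome) == 1L)
  withr::with_seed(rng_seed, {
    G <- nchar(genome)
    rl <- params$read_length
    n_pairs <- max(1L, as.integer(round(params$coverage * G / (2 * rl))))
    fl <- as.integer(round(stats::rnorm(n_pairs, params$fragment_mean,
                                        params$fragment_sd)))
    fl <- pmin(pmax(fl, rl), G)
    start <- vapply(G - fl + 1L,
                    function(m) sample.int(m, 1L), integer(1))
    frags <- substring(genome, start, start + fl - 1L)
    flip <- stats::runif(n_pairs) < 0.5
    frags[flip] <- reverse_complement(frags[flip])
    r1 <- substr(frags, 1L, rl)
    r2 <- reverse_complement(substr(frags, fl - rl + 1L, fl))

    inject_errors <- function(reads) {
      if (params$error_rate <= 0) return(reads)
      n_err <- stats::rbinom(length(reads), rl, params$error_rate)
      for (i in which(n_err > 0L)) {
        pos <- sample.int(rl, n_err[i])
        ch <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
        reads[i] <- paste(.substitute_bases(ch, pos), collapse = "")
      }
      reads
    }
    r1 <- inject_errors(r1)
    r2 <- inject_errors(r2)
    q <- strrep("I", rl)
    ids <- sprintf("%s_%d", id_prefix, seq_len(n_pairs))
    list(r1 = data.frame(id = paste0(ids, "/1"), seq = r1, qual = q,
                         stringsAsFactors = FALSE),
         r2 = data.frame(id = paste0(ids, "/2"), seq = r2, qual = q,
                         stringsAsFactors = FALSE))
  })
}

#' Score assembled contigs against the simulated truth
#'
#' Each contig is placed on the male genome by exact match (either
#' orientation; first occurrence). Recall is the fraction of truth-interval
#' bases covered by placed contigs. Precision is the fraction of contig
#' bases lying within truth intervals extended by k-1 on each side (the
#' shared flanks a correct contig legitimately carries); contigs matching
#' nowhere count wholly against precision.
#'
#' @param contigs data.frame from [assemble()]/[filter_and_rank()].
#' @param pair A `genome_pair`.
#' @param k K-mer size used by the pipeline (flank width is k-1).
#' @return List with `recall`, `precision`, `n_contigs`, `n_unplaced`.
#' @export
evaluate_against_truth <- function(contigs, pair, k = 27L) {
  stopifnot(inherits(pair, "genome_pair"))
  male <- unname(pair$male_genome)
  G <- nchar(male)
  truth <- pair$y_intervals
  truth_mask <- logical(G)
  ext_mask <- logical(G)
  for (i in seq_len(nrow(truth))) {
    truth_mask[(truth$start[i] + 1L):truth$end[i]] <- TRUE
    lo <- max(truth$start[i] - (k - 1L), 0L)
    hi <- min(truth$end[i] + (k - 1L), G)
    ext_mask[(lo + 1L):hi] <- TRUE
  }
  covered <- logical(G)
  n_unplaced <- 0L
  n_precise <- 0
  n_total <- 0
  for (s in contigs$sequence) {
    pos <- regexpr(s, male, fixed = TRUE)
    if (pos == -1L) pos <- regexpr(reverse_complement(s), male, fixed = TRUE)
    n_total <- n_total + nchar(s)
    if (pos == -1L) {
      n_unplaced <- n_unplaced + 1L
      next
    }
    idx <- pos:(pos + nchar(s) - 1L)
    covered[idx] <- TRUE
    n_precise <- n_precise + sum(ext_mask[idx])
  }
  recall <- if (any(truth_mask)) {
    sum(covered & truth_mask) / sum(truth_mask)
  } else NA_real_
  precision <- if (n_total > 0) n_precise / n_total else NA_real_
  list(recall = recall, precision = precision,
       n_contigs = nrow(contigs), n_unplaced = n_unplaced)
}
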