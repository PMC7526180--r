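#' Reassemble sex-specific k-mers into contigs (inchworm)
#'
#' Greedy single-path assembly over the stranded expansion of a canonical
#' k-mer set. A focal k-mer is extended one base at a time, rightwards then
#' leftwards, for as long as exactly one unused k-mer overlaps the current
#' end by k-1 bases; any ambiguity (zero or several candidates) terminates
#' the extension. Consuming a k-mer in one orientation consumes its reverse
#' complement too, so every input k-mer ends up in exactly one contig and
#' the output is independent of the strand in which sequence was supplied.
#'
#' @param table `kmer_table` of (typically male-unique) canonical k-mers.
#' @param seed_order `"sorted"` picks focal k-mers in lexicographic order
#'   (bit-identical across runs); `"random"` shuffles the focal order under
#'   `rng_seed`, reproducing the historical take-a-k-mer-at-random scheme.
#' @param rng_seed Integer seed used when `seed_order = "random"`.
#' @param id_prefix Prefix for contig ids; ids follow the pattern
#'   `<prefix>_<serial>_X<round(mean coverage)>_<length>`.
#' @return data.frame with columns `id`, `sequence` (canonical
#'   orientation), `length`, `mean_kmer_count`.
#' @examples
#' tab <- count_kmers("AACCA", k = 3)
#' assemble(tab)
#' @export
assemble <- function(table, seed_order = c("sorted", "random"),
                     rng_seed = 1L, id_prefix = "ksub") {
  stopifnot(inherits(table, "kmer_table"))
  seed_order <- match.arg(seed_order)
  canon <- table$counts$kmer
  n <- length(canon)
  if (n == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      length = integer(0), mean_kmer_count = numeric(0),
                      stringsAsFactors = FALSE))
  }
  k <- table$k
  rc <- reverse_complement(canon)
  all_kmers <- c(canon, rc)            # stranded expansion
  partner <- c(n + seq_len(n), seq_len(n))
  pref <- substr(all_kmers, 1L, k - 1L)
  suf <- substr(all_kmers, 2L, k)
  pre_idx <- list2env(split(seq_len(2L * n), pref), hash = TRUE)
  suf_idx <- list2env(split(seq_len(2L * n), suf), hash = TRUE)
  first_base <- substr(all_kmers, 1L, 1L)
  last_base <- substr(all_kmers, k, k)
  used <- logical(2L * n)

  focal_order <- if (seed_order == "sorted") seq_len(n) else {
    withr::with_seed(rng_seed, sample.int(n))
  }

  seqs <- character(n)
  n_contigs <- 0L
  for (f in focal_order) {
    if (used[f]) next
    used[f] <- used[partner[f]] <- TRUE
    right <- character(0)
    left <- character(0)
    # rightward: candidates are unused k-mers whose (k-1)-prefix equals the
    # current (k-1)-suffix; extension only while exactly one exists
    cur <- suf[f]
    repeat {
      cand <- get0(cur, envir = pre_idx, ifnotfound = NULL)
      cand <- cand[!used[cand]]
      if (length(cand) != 1L) break
      used[cand] <- used[partner[cand]] <- TRUE
      right <- c(right, last_base[cand])
      cur <- suf[cand]
    }
    # leftward, symmetric
    cur <- pref[f]
    repeat {
      cand <- get0(cur, envir = suf_idx, ifnotfound = NULL)
      cand <- cand[!used[cand]]
      if (length(cand) != 1L) break
      used[cand] <- used[partner[cand]] <- TRUE
      left <- c(left, first_base[cand])
      cur <- pref[cand]
    }
    n_contigs <- n_contigs + 1L
    seqs[n_contigs] <- paste(c(rev(left), all_kmers[f], right),
                             collapse = "")
  }
  seqs <- seqs[seq_len(n_contigs)]
  seqs <- canonical_kmer(seqs)         # canonical orientation of contigs

  lens <- nchar(seqs)
  meancov <- vapply(seqs, function(s) {
    wins <- canonical_kmer(substring(s, 1:(nchar(s) - k + 1L),
                                     k:nchar(s)))
    mean(table$counts[list(wins), on = "kmer"]$count)
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(
    id = sprintf("%s_%d_X%d_%d", id_prefix, seq_len(n_contigs),
                 round(meancov), lens),
    sequence = seqs, length = lens, mean_kmer_count = meancov,
    stringsAsFactors = FALSE)
}

#' Filter contigs by length and keep the longest
#'
#' Drops contigs shorter than `min_length`, sorts the rest by decreasing
#' length (ties broken by ascending id) and returns the first `top_n` —
#' the selection step used to pick contigs long enough for robust primer
#' design.
#'
#' @param contigs data.frame from [assemble()].
#' @param min_length Minimum contig length in bp (default 80).
#' @param top_n Number of contigs to keep (default all).
#' @return Filtered, ranked data.frame of contigs.
#' @export
filter_and_rank <- function(contigs, min_length = 80L, top_n = Inf) {
  stopifnot(is.data.frame(contigs), top_n >= 1L)
  keep <- contigs[contigs$length >= min_length, , drop = FALSE]
  keep <- keep[order(-keep$length, keep$id), , drop = FALSE]
  head_n <- min(nrow(keep), top_n)
  out <- keep[seq_len(head_n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write contigs to FASTA with length/coverage attributes
#'
#' @param contigs data.frame from [assemble()] or [filter_and_rank()].
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  seqs <- contigs$sequence
  names(seqs) <- sprintf("%s length=%d meancov=%.2f", contigs$id,
                         contigs$length, contigs$mean_kmer_count)
  write_fasta(seqs, path)
}
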