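#' @import data.table
NULL

new_kmer_table <- function(k, counts, n_skipped = 0L) {
  stopifnot(data.table::is.data.table(counts),
            identical(names(counts), c("kmer", "count")))
  structure(list(k = as.integer(k), counts = counts,
                 n_skipped = as.integer(n_skipped)),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat("k-mer count table (k = ", x$k, ")\n", sep = "")
  cat("  distinct k-mers: ", nrow(x$counts),
      "; total instances: ", sum(as.numeric(x$counts$count)),
      "; N-containing windows skipped: ", x$n_skipped, "\n", sep = "")
  invisible(x)
}

# canonical form: lexicographically smaller of a k-mer and its reverse
# complement (A < C < G < T byte order)
canonical_kmer <- function(x) {
  rc <- reverse_complement(x)
  ifelse(x <= rc, x, rc)
}

#' Count canonical k-mers in fragments
#'
#' Every window of length `k` containing only `{A,C,G,T}` contributes one
#' count to its canonical form (the lexicographically smaller of the window
#' and its reverse complement, so both strands are merged). Windows
#' containing `N` are skipped and tallied in the `n_skipped` field.
#'
#' @param fragments Character vector of DNA sequences, or a data.frame with
#'   a `seq` column as produced by [merge_pairs()].
#' @param k Odd integer k-mer size, at least 3 (default 27).
#' @return A `kmer_table`: list with `k`, `counts` (a data.table with
#'   columns `kmer`, `count`, sorted by `kmer`) and `n_skipped`.
#' @examples
#' count_kmers("ACGTA", k = 3)$counts
#' @export
count_kmers <- function(fragments, k = 27L) {
  if (is.data.frame(fragments)) fragments <- fragments$seq
  stopifnot(is.character(fragments))
  k <- as.integer(k)
  if (k < 3L || k %% 2L == 0L) {
    stop("`k` must be an odd integer >= 3 (odd so no k-mer is its own ",
         "reverse complement)", call. = FALSE)
  }
  lens <- nchar(fragments)
  keep <- lens >= k
  if (!any(keep)) {
    warning("k = ", k, " exceeds every fragment length; empty table")
    return(new_kmer_table(k, data.table::data.table(kmer = character(0),
                                                    count = integer(0))))
  }
  wins <- unlist(lapply(fragments[keep], function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  has_n <- grepl("N", wins, fixed = TRUE)
  n_skipped <- sum(has_n)
  wins <- wins[!has_n]
  if (length(wins) == 0L) {
    return(new_kmer_table(k, data.table::data.table(kmer = character(0),
                                                    count = integer(0)),
                          n_skipped))
  }
  u <- unique(wins)
  canon_u <- canonical_kmer(u)
  kmer <- canon_u[match(wins, u)]
  dt <- data.table::data.table(kmer = kmer)
  dt <- dt[, list(count = .N), by = "kmer"]
  data.table::setkeyv(dt, "kmer")
  new_kmer_table(k, dt, n_skipped)
}

#' Build the k-mer spectrum (multiplicity histogram)
#'
#' @param table A `kmer_table` from [count_kmers()].
#' @return A `kmer_spectrum`: list with `k` and `histogram`, a data.table
#'   mapping `multiplicity` to `n_distinct` (number of distinct k-mers seen
#'   at that multiplicity), sorted by multiplicity.
#' @export
build_spectrum <- function(table) {
  stopifnot(inherits(table, "kmer_table"))
  if (nrow(table$counts) == 0L) stop("empty k-mer table", call. = FALSE)
  count <- NULL # NSE
  h <- table$counts[, list(n_distinct = .N), by = list(multiplicity = count)]
  data.table::setkeyv(h, "multiplicity")
  structure(list(k = table$k, histogram = h), class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("k-mer spectrum (k = ", x$k, "), ",
      sum(x$histogram$n_distinct), " distinct k-mers, multiplicities ",
      min(x$histogram$multiplicity), "-", max(x$histogram$multiplicity),
      "\n", sep = "")
  invisible(x)
}

#' Plot a k-mer spectrum
#'
#' @param x A `kmer_spectrum`.
#' @param log Axes to log-scale, as in [graphics::plot()] (default `"y"`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.kmer_spectrum <- function(x, log = "y", ...) {
  graphics::plot(x$histogram$multiplicity, x$histogram$n_distinct,
                 type = "h", log = log, xlab = "k-mer multiplicity",
                 ylab = "distinct k-mers", ...)
  invisible(x)
}

# dense histogram vector h[m] for m = 1..max multiplicity
.dense_hist <- function(spectrum) {
  m <- spectrum$histogram$multiplicity
  h <- numeric(max(m))
  h[m] <- spectrum$histogram$n_distinct
  h
}

#' Find the error-valley threshold of a k-mer spectrum
#'
#' Sequencing errors pile up at low multiplicities (mostly 1), genuine
#' genomic k-mers peak near the sequencing depth; the valley between the
#' two is the natural cutoff. Returns the smallest multiplicity `m` in
#' `[2, max_search]` with `h[m] <= h[m-1]` and `h[m] < h[m+1]` (first
#' strict local minimum to the right of the error peak), on the histogram
#' with absent bins filled with zero. K-mers with count below the returned
#' threshold are to be discarded with [filter_by_count()].
#'
#' @param spectrum A `kmer_spectrum`.
#' @param max_search Largest multiplicity to search (default 1000).
#' @param smooth Apply a centred 3-bin running median before the minimum
#'   search (default `FALSE`); real spectra are noisy, toy ones are not.
#' @return Integer threshold `t`.
#' @export
find_error_threshold <- function(spectrum, max_search = 1000L,
                                 smooth = FALSE) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  h <- .dense_hist(spectrum)
  if (smooth && length(h) >= 3L) h <- stats::runmed(h, 3L)
  # a valley only exists to the right of a count-1 error peak; a spectrum
  # that rises from the origin (e.g. error-free data) has none, and
  # searching it would latch onto sampling noise in the tail
  has_error_peak <- length(h) >= 2L && h[1L] > h[2L]
  top <- min(max_search, length(h) - 1L)
  if (has_error_peak) {
    for (m in seq_len(max(top - 1L, 0L)) + 1L) {
      if (h[m] <= h[m - 1L] && h[m] < h[m + 1L]) return(as.integer(m))
    }
  }
  stop(structure(class = c("ksub_no_valley_error", "error", "condition"),
                 list(message = paste0(
                   "no valley found in the k-mer spectrum within ",
                   "multiplicity [2, ", max_search, "]; the spectrum looks ",
                   "monotone. Set the threshold manually."),
                   call = sys.call(-1L))))
}

#' Drop low-count k-mers
#'
#' Removes entries with count below `t` (the paper-style rule: "counts less
#' than t" are considered sequencing errors). The input is not modified.
#'
#' @param table A `kmer_table`.
#' @param t Minimum retained count, >= 1.
#' @return A new `kmer_table` with exactly the entries of count >= `t`.
#' @export
filter_by_count <- function(table, t) {
  stopifnot(inherits(table, "kmer_table"), t >= 1L)
  count <- NULL # NSE
  new_kmer_table(table$k, table$counts[count >= t], table$n_skipped)
}

#' Estimate sequencing depth and genome size from a k-mer spectrum
#'
#' Above the error threshold the spectrum's mode sits at the effective
#' k-mer depth `c`; dividing the total retained k-mer instances by `c`
#' estimates the (unique) genome length in k-mer positions.
#'
#' @param spectrum A `kmer_spectrum`.
#' @param t Error threshold, e.g. from [find_error_threshold()].
#' @return A `spectrum_summary`: list with `error_threshold`,
#'   `genomic_peak`, `genome_size` and `total_retained_instances`.
#' @export
estimate_coverage_and_genome_size <- function(spectrum, t) {
  stopifnot(inherits(spectrum, "kmer_spectrum"), t >= 1L)
  multiplicity <- NULL # NSE
  h <- spectrum$histogram[multiplicity >= t]
  if (nrow(h) == 0L) stop("no k-mers at or above the threshold", call. = FALSE)
  peak <- h$multiplicity[which.max(h$n_distinct)]
  total <- sum(as.numeric(h$multiplicity) * as.numeric(h$n_distinct))
  structure(list(error_threshold = as.integer(t),
                 genomic_peak = as.integer(peak),
                 genome_size = round(total / peak),
                 total_retained_instances = total),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("spectrum summary: threshold ", x$error_threshold,
      ", depth peak ", x$genomic_peak, "x, genome size estimate ",
      format(x$genome_size, big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Write / read a k-mer count table as sorted `kmer<TAB>count` text
#'
#' @param table A `kmer_table`.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path` invisibly (write) or a `kmer_table` (read).
#' @export
write_kmer_table <- function(table, path) {
  stopifnot(inherits(table, "kmer_table"))
  data.table::fwrite(table$counts, path, sep = "\t", col.names = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' @rdname write_kmer_table
#' @export
read_kmer_table <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  df <- tryCatch(
    utils::read.table(con, header = FALSE, sep = "\t",
                      col.names = c("kmer", "count"),
                      colClasses = c("character", "integer"),
                      quote = "", comment.char = ""),
    error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0L) {
    stop("empty k-mer table file: ", path, call. = FALSE)
  }
  dt <- data.table::as.data.table(df)
  data.table::setkeyv(dt, "kmer")
  new_kmer_table(nchar(dt$kmer[1L]), dt)
}
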