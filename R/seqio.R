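#' Reverse-complement DNA sequences
#'
#' Watson-Crick complement, reversed. `N` maps to `N`. Vectorised.
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement(c("GTA", "ACGT"))
#' @export
reverse_complement <- function(x) {
  if (!is.character(x)) stop("`x` must be a character vector of DNA sequences")
  if (length(x) == 0L) return(character(0))
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("invalid sequence: non-ACGTN character in element ",
         which(bad)[1L], call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file, optionally gzip-compressed.
#' @return Named character vector of sequences (names are the full header
#'   lines without the leading `>`).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  out <- as.character(ss)
  names(out) <- names(ss)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(ss) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(ss, filepath = path, format = "fasta",
                              width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to a 4-line FASTQ file (Phred+33), optionally gzipped.
#' @return A data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(ss)$qualities)
  data.frame(id = sub("\\s.*$", "", names(ss)),
             seq = as.character(ss),
             qual = qual,
             stringsAsFactors = FALSE)
}

#' Read a pair of mate FASTQ files in lockstep
#'
#' @param path_r1,path_r2 Paths to the forward and reverse mate files.
#' @return List with elements `r1` and `r2`, each as from [read_fastq()].
#' @export
read_fastq_pairs <- function(path_r1, path_r2) {
  r1 <- read_fastq(path_r1)
  r2 <- read_fastq(path_r2)
  if (nrow(r1) != nrow(r2)) {
    stop("mate-count mismatch: ", nrow(r1), " records in ", path_r1,
         " vs ", nrow(r2), " in ", path_r2, call. = FALSE)
  }
  id1 <- sub("/[12]$", "", r1$id)
  id2 <- sub("/[12]$", "", r2$id)
  if (!identical(id1, id2)) {
    bad <- which(id1 != id2)[1L]
    stop("mate id mismatch at record ", bad, ": '", r1$id[bad],
         "' vs '", r2$id[bad], "'", call. = FALSE)
  }
  list(r1 = r1, r2 = r2)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with `id`, `seq`, `qual` columns.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$id
  Biostrings::writeXStringSet(ss, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# Merge a single pair given raw byte vectors. Returns merged sequence or NULL.
.merge_one <- function(raw1, rawrc2, rawq1, rawqrc2, min_overlap,
                       max_mismatch_frac) {
  n1 <- length(raw1)
  n2 <- length(rawrc2)
  for (ov in seq.int(min(n1, n2), min_overlap)) {
    a <- raw1[(n1 - ov + 1L):n1]
    b <- rawrc2[1:ov]
    mism <- a != b
    if (sum(mism) <= max_mismatch_frac * ov) {
      # consensus over the overlap: higher-quality base wins, ties to r1
      cons <- a
      if (any(mism) && !is.null(rawq1) && !is.null(rawqrc2)) {
        qa <- rawq1[(n1 - ov + 1L):n1]
        qb <- rawqrc2[1:ov]
        take_b <- mism & (qb > qa)
        cons[take_b] <- b[take_b]
      }
      merged <- c(raw1[seq_len(n1 - ov)], cons,
                  if (ov < n2) rawrc2[(ov + 1L):n2])
      return(rawToChar(as.raw(merged)))
    }
  }
  NULL
}

#' Merge overlapping read pairs into fragments
#'
#' Reverse-complements each reverse mate and scans for the longest
#' suffix-of-r1 / prefix-of-rc(r2) overlap of length at least `min_overlap`
#' whose mismatch fraction does not exceed `max_mismatch_frac`. Qualifying
#' pairs are emitted as one merged fragment (disagreeing overlap bases are
#' taken from the higher-quality read when qualities are present, otherwise
#' from r1); pairs with no qualifying overlap contribute both mates as
#' separate fragments, so no sequence is discarded.
#'
#' @param r1,r2 data.frames of forward and reverse reads (columns `id`,
#'   `seq` and optionally `qual`), as from [read_fastq_pairs()]. `r2` is the
#'   reverse-strand mate as sequenced.
#' @param min_overlap Minimum overlap length in bp (default 10).
#' @param max_mismatch_frac Maximum mismatch fraction tolerated within the
#'   overlap (default 0.1).
#' @return data.frame with columns `id`, `seq` and `source` (one of
#'   `merged`, `unmerged_r1`, `unmerged_r2`).
#' @examples
#' r1 <- data.frame(id = "p", seq = "AACCGGTT", qual = NA)
#' r2 <- data.frame(id = "p", seq = "CCAACC", qual = NA)
#' merge_pairs(r1, r2, min_overlap = 4, max_mismatch_frac = 0)
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10L, max_mismatch_frac = 0.1) {
  stopifnot(nrow(r1) == nrow(r2), min_overlap >= 1L,
            max_mismatch_frac >= 0, max_mismatch_frac <= 1)
  has_q1 <- "qual" %in% names(r1) && !all(is.na(r1$qual))
  has_q2 <- "qual" %in% names(r2) && !all(is.na(r2$qual))
  check_qual <- function(df, which) {
    if (!"qual" %in% names(df)) return(invisible())
    ok <- is.na(df$qual) | nchar(df$qual) == nchar(df$seq)
    if (!all(ok)) {
      stop("malformed record: quality length differs from sequence length ",
           "for read '", df$id[which(!ok)[1L]], "' (", which, ")",
           call. = FALSE)
    }
  }
  check_qual(r1, "r1")
  check_qual(r2, "r2")

  rc2 <- reverse_complement(r2$seq)
  n <- nrow(r1)
  out_id <- character(2L * n)
  out_seq <- character(2L * n)
  out_src <- character(2L * n)
  j <- 0L
  for (i in seq_len(n)) {
    raw1 <- as.integer(charToRaw(r1$seq[i]))
    rawrc2 <- as.integer(charToRaw(rc2[i]))
    q1 <- if (has_q1 && !is.na(r1$qual[i])) as.integer(charToRaw(r1$qual[i]))
    qrc2 <- if (has_q2 && !is.na(r2$qual[i]))
      rev(as.integer(charToRaw(r2$qual[i])))
    merged <- if (min(length(raw1), length(rawrc2)) >= min_overlap) {
      .merge_one(raw1, rawrc2, q1, qrc2, min_overlap, max_mismatch_frac)
    }
    if (!is.null(merged)) {
      j <- j + 1L
      out_id[j] <- r1$id[i]
      out_seq[j] <- merged
      out_src[j] <- "merged"
    } else {
      out_id[j + 1L] <- r1$id[i]
      out_seq[j + 1L] <- r1$seq[i]
      out_src[j + 1L] <- "unmerged_r1"
      out_id[j + 2L] <- r2$id[i]
      out_seq[j + 2L] <- r2$seq[i]
      out_src[j + 2L] <- "unmerged_r2"
      j <- j + 2L
    }
  }
  data.frame(id = out_id[seq_len(j)], seq = out_seq[seq_len(j)],
             source = out_src[seq_len(j)], stringsAsFactors = FALSE)
}
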