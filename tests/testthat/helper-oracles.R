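# Independent brute-force oracles, deliberately implemented with different
# machinery than the package (chartr + per-window loops + environments).

oracle_revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

oracle_canonical <- function(s) {
  rc <- oracle_revcomp(s)
  ifelse(s <= rc, s, rc)
}

# naive window-iteration dictionary counter
oracle_count_kmers <- function(frags, k) {
  env <- new.env(hash = TRUE)
  for (s in frags) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (grepl("N", w, fixed = TRUE)) next
      w <- oracle_canonical(w)
      env[[w]] <- (if (is.null(env[[w]])) 0L else env[[w]]) + 1L
    }
  }
  keys <- sort(ls(env))
  stats::setNames(vapply(keys, function(kk) env[[kk]], integer(1)), keys)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# build a kmer_table directly from keys/counts (keys need not be canonical;
# used for set-algebra tests where only key identity matters)
make_table <- function(keys, counts, k = nchar(keys[1])) {
  dt <- data.table::data.table(kmer = keys, count = as.integer(counts))
  data.table::setkeyv(dt, "kmer")
  ksubtract:::new_kmer_table(k, dt)
}

# spectrum built directly from a multiplicity histogram
make_spectrum <- function(multiplicity, n_distinct, k = 27L) {
  h <- data.table::data.table(multiplicity = as.integer(multiplicity),
                              n_distinct = as.numeric(n_distinct))
  data.table::setkeyv(h, "multiplicity")
  structure(list(k = k, histogram = h), class = "kmer_spectrum")
}
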