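#' Subtract shared k-mers from the heterogametic set
#'
#' Removes every k-mer present in the female (homogametic) table from the
#' male (heterogametic) table, leaving the Y-enriched set. Membership is
#' decided by key only; multiplicities play no role. Both inputs are
#' expected to have been filtered by their own error thresholds first.
#'
#' @param male,female `kmer_table`s with the same `k`.
#' @return List with `unique` (a `kmer_table` of male-only k-mers, male
#'   counts retained, sorted) and `summary` (a `subtraction_summary` with
#'   `n_male_retained`, `n_female_retained`, `n_shared`, `n_male_unique`).
#' @examples
#' m <- count_kmers("AACCAGG", k = 3)
#' f <- count_kmers("AACCA", k = 3)
#' subtract_kmers(m, f)$summary
#' @export
subtract_kmers <- function(male, female) {
  stopifnot(inherits(male, "kmer_table"), inherits(female, "kmer_table"))
  if (male$k != female$k) {
    stop("k mismatch: male k = ", male$k, ", female k = ", female$k,
         call. = FALSE)
  }
  uq <- male$counts[!female$counts, on = "kmer"]
  data.table::setkeyv(uq, "kmer")
  summary <- structure(list(
    n_male_retained = nrow(male$counts),
    n_female_retained = nrow(female$counts),
    n_shared = nrow(male$counts) - nrow(uq),
    n_male_unique = nrow(uq)), class = "subtraction_summary")
  list(unique = new_kmer_table(male$k, uq, male$n_skipped),
       summary = summary)
}

#' @export
print.subtraction_summary <- function(x, ...) {
  cat("k-mer subtraction:\n",
      "  male retained:   ", x$n_male_retained, "\n",
      "  female retained: ", x$n_female_retained, "\n",
      "  shared:          ", x$n_shared, "\n",
      "  male-unique:     ", x$n_male_unique, "\n", sep = "")
  invisible(x)
}
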