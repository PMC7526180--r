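.find_fixed <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# all products on the given strand: forward primer occurrence followed by a
# downstream occurrence of rc(reverse); 0-based half-open coordinates
.pcr_one_strand <- function(template, forward, reverse, max_product) {
  f_starts <- .find_fixed(forward, template) - 1L
  r_ends <- .find_fixed(reverse_complement(reverse), template) - 1L +
    nchar(reverse)
  if (length(f_starts) == 0L || length(r_ends) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  grid <- expand.grid(start = f_starts, end = r_ends)
  size <- grid$end - grid$start
  grid[size > 0 & size <= max_product, , drop = FALSE]
}

#' In-silico PCR over a template
#'
#' Exact-match electronic PCR: finds every occurrence of the forward primer
#' and every downstream occurrence of the reverse complement of the reverse
#' primer, on both strands of the template, and reports one product per
#' qualifying combination. Product size includes both primer footprints.
#' No mismatch or thermodynamic model: the intended use is verifying
#' subtraction contigs against primers designed on those same contigs.
#'
#' @param template DNA sequence (single string), e.g. a contig.
#' @param forward,reverse Primer sequences, both written 5'->3'.
#' @param max_product Largest product size reported (default 2000 bp).
#' @param template_id Id echoed into the result.
#' @return data.frame with columns `template_id`, `start`, `end` (0-based
#'   half-open template coordinates on the reported strand), `strand`
#'   (`+`/`-`), `product_size`, `n_sites` (number of products found on this
#'   template); sorted by product size. Zero rows when nothing amplifies.
#' @examples
#' insilico_pcr("AAGGCCTTACGCGCGT", "AAGGC", "ACGCG")
#' @export
insilico_pcr <- function(template, forward, reverse, max_product = 2000L,
                         template_id = "template") {
  stopifnot(is.character(template), length(template) == 1L,
            nchar(forward) >= 1L, nchar(reverse) >= 1L)
  if (grepl("[^ACGTN]", template)) {
    stop("template contains non-ACGTN characters", call. = FALSE)
  }
  if (grepl("[^ACGT]", forward) || grepl("[^ACGT]", reverse)) {
    stop("primers must be over {A,C,G,T}", call. = FALSE)
  }
  plus <- .pcr_one_strand(template, forward, reverse, max_product)
  minus <- .pcr_one_strand(reverse_complement(template), forward, reverse,
                           max_product)
  out <- rbind(
    if (nrow(plus)) data.frame(strand = "+", plus),
    if (nrow(minus)) data.frame(strand = "-", minus))
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      product_size = integer(0), n_sites = integer(0),
                      stringsAsFactors = FALSE))
  }
  out$product_size <- out$end - out$start
  out <- out[order(out$product_size, out$strand, out$start), , drop = FALSE]
  data.frame(template_id = template_id, start = out$start, end = out$end,
             strand = out$strand, product_size = out$product_size,
             n_sites = nrow(out), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Run a primer panel against a set of templates
#'
#' @param templates Named character vector of template sequences (e.g. from
#'   [read_fasta()]).
#' @param primers data.frame with columns `name`, `forward`, `reverse`,
#'   e.g. from [read_primers()].
#' @param max_product Largest product size reported (default 2000 bp).
#' @return data.frame of amplicons with a `primer_name` column prepended;
#'   primer/template combinations with no product are absent.
#' @export
pcr_screen <- function(templates, primers, max_product = 2000L) {
  stopifnot(!is.null(names(templates)),
            all(c("name", "forward", "reverse") %in% names(primers)))
  res <- list()
  for (i in seq_len(nrow(primers))) {
    for (j in seq_along(templates)) {
      hit <- insilico_pcr(templates[[j]], primers$forward[i],
                          primers$reverse[i], max_product,
                          template_id = names(templates)[j])
      if (nrow(hit)) {
        res[[length(res) + 1L]] <- data.frame(primer_name = primers$name[i],
                                              hit)
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(primer_name = character(0), template_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), product_size = integer(0),
                      n_sites = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Read a primer table (`name<TAB>forward<TAB>reverse`)
#'
#' @param path Path to a 3-column TSV, with or without a header line.
#' @return data.frame with columns `name`, `forward`, `reverse`.
#' @export
read_primers <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^name\t", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  names(df) <- c("name", "forward", "reverse")[seq_len(ncol(df))]
  df$forward <- toupper(df$forward)
  df$reverse <- toupper(df$reverse)
  df
}

#' Percent divergence between two aligned sequences
#'
#' Proportion of differing sites (p-distance) as a percentage, over the
#' columns where neither sequence has a gap (`-`) or `N`.
#'
#' @param a,b Aligned DNA sequences of equal length.
#' @return Percentage in `[0, 100]`; `NA` if no comparable column exists.
#' @examples
#' p_distance("ACGT", "ACGA")
#' @export
p_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) {
    stop("sequences must be pre-aligned to equal length (got ", nchar(a),
         " and ", nchar(b), " bp)", call. = FALSE)
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  comparable <- !(ca %in% c("-", "N")) & !(cb %in% c("-", "N"))
  if (!any(comparable)) {
    warning("no comparable columns")
    return(NA_real_)
  }
  100 * mean(ca[comparable] != cb[comparable])
}
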