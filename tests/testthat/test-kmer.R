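test_that("count_kmers canonicalises windows and skips N", {
  tab <- count_kmers("ACGTA", k = 3)
  expect_identical(as.list(stats::setNames(tab$counts$count,
                                           tab$counts$kmer)),
                   list(ACG = 2L, GTA = 1L))
  expect_warning(tab <- count_kmers("AA", k = 3), "empty table")
  expect_identical(nrow(tab$counts), 0L)
  tab <- count_kmers("AANAA", k = 3)
  expect_identical(nrow(tab$counts), 0L)
  expect_identical(tab$n_skipped, 3L)
  expect_error(count_kmers("ACGT", k = 4), "odd")
})

test_that("count_kmers matches the naive window dictionary", {
  set.seed(21)
  frags <- vapply(sample(30:500, 30, replace = TRUE), random_dna,
                  character(1))
  tab <- count_kmers(frags, k = 27)
  oracle <- oracle_count_kmers(frags, 27)
  expect_identical(tab$counts$kmer, names(oracle))
  expect_identical(tab$counts$count, unname(oracle))
  expect_identical(sum(tab$counts$count),
                   sum(pmax(nchar(frags) - 26L, 0L)))
})

test_that("count tables are invariant to fragment strand", {
  set.seed(8)
  frags <- vapply(sample(40:120, 25, replace = TRUE), random_dna,
                  character(1))
  a <- count_kmers(frags, k = 27)
  b <- count_kmers(reverse_complement(frags), k = 27)
  expect_identical(a$counts, b$counts)
})

test_that("build_spectrum is the exact multiplicity histogram", {
  tab <- count_kmers("ACGTA", k = 3) # {ACG:2, GTA:1}
  sp <- build_spectrum(tab)
  expect_identical(sp$histogram$multiplicity, c(1L, 2L))
  expect_identical(sp$histogram$n_distinct, c(1L, 1L))
  set.seed(2)
  tab <- count_kmers(vapply(rep(200, 10), random_dna, character(1)), k = 9)
  sp <- build_spectrum(tab)
  expect_identical(sum(sp$histogram$n_distinct), nrow(tab$counts))
})

test_that("the error valley is the first local minimum after the error peak", {
  bimodal <- make_spectrum(1:8, c(10000, 3000, 900, 400, 550, 800, 700, 400))
  expect_identical(find_error_threshold(bimodal), 4L)
  expect_identical(find_error_threshold(make_spectrum(1:4, c(100, 50, 60, 40))),
                   2L)
  # strictly decreasing: no valley
  expect_error(find_error_threshold(make_spectrum(1:6, c(64, 32, 16, 8, 4, 2))),
               class = "ksub_no_valley_error")
  # rising from the origin (no error peak): no valley either
  expect_error(find_error_threshold(make_spectrum(1:8, c(5, 40, 200, 500, 600, 400, 150, 30))),
               class = "ksub_no_valley_error")
  # a one-bin glitch in the descent fools the raw rule; the median
  # smoother rides over it to the real valley
  glitchy <- make_spectrum(1:9, c(10000, 4000, 4500, 1500, 400, 550, 800, 700, 300))
  expect_identical(find_error_threshold(glitchy), 2L)
  expect_identical(find_error_threshold(glitchy, smooth = TRUE), 6L)
})

test_that("filter_by_count keeps exactly the entries at or above t", {
  tab <- make_table(c("AAA", "CCC", "GGG"), c(1, 2, 5))
  f <- filter_by_count(tab, 2)
  expect_identical(f$counts$kmer, c("CCC", "GGG"))
  expect_identical(filter_by_count(tab, 1)$counts, tab$counts)
  set.seed(4)
  for (i in 1:20) {
    keys <- unique(vapply(rep(7, 50), random_dna, character(1)))
    tab <- make_table(keys, sample(1:10, length(keys), replace = TRUE))
    t <- sample(1:10, 1)
    kept <- filter_by_count(tab, t)
    expect_identical(nrow(kept$counts) +
                       sum(tab$counts$count < t), nrow(tab$counts))
    expect_true(all(kept$counts$count >= t))
  }
})

test_that("coverage peak and genome size come from the retained spectrum", {
  sp <- make_spectrum(20, 9974)
  s <- estimate_coverage_and_genome_size(sp, t = 4)
  expect_identical(s$genomic_peak, 20L)
  expect_identical(s$genome_size, 9974)
  # doubling every bin doubles G and leaves the peak unchanged
  sp2 <- make_spectrum(sp$histogram$multiplicity,
                       2 * sp$histogram$n_distinct)
  s2 <- estimate_coverage_and_genome_size(sp2, t = 4)
  expect_identical(s2$genomic_peak, s$genomic_peak)
  expect_identical(s2$genome_size, 2 * s$genome_size)
  expect_error(estimate_coverage_and_genome_size(make_spectrum(1, 10), 5),
               "threshold")
})

test_that("genome size is recovered from uniform error-free depth", {
  set.seed(77)
  genome <- random_dna(50000)
  tab <- count_kmers(genome, k = 27)
  # uniform 15x k-mer depth of a unique genome: every k-mer at count 15
  tab$counts$count <- 15L * tab$counts$count
  s <- estimate_coverage_and_genome_size(build_spectrum(tab), t = 2)
  expect_identical(s$genomic_peak, 15L)
  expect_lt(abs(s$genome_size - (50000 - 26)) / (50000 - 26), 0.05)
})

test_that("k-mer tables round-trip through the sorted TSV format", {
  set.seed(14)
  tab <- count_kmers(vapply(rep(300, 5), random_dna, character(1)), k = 13)
  dir <- withr::local_tempdir()
  for (ext in c("tsv", "tsv.gz")) {
    p <- file.path(dir, paste0("t.", ext))
    write_kmer_table(tab, p)
    back <- read_kmer_table(p)
    expect_identical(back$counts, tab$counts)
    expect_identical(back$k, tab$k)
  }
})
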