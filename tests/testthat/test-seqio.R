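test_that("reverse_complement complements, reverses, and maps N to N", {
  expect_identical(reverse_complement("GTA"), "TAC")
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("ANC"), "GNT")
  expect_error(reverse_complement("ACGU"), "invalid sequence")
})

test_that("reverse_complement is an involution and preserves length", {
  set.seed(11)
  s <- vapply(sample(1:80, 60, replace = TRUE), random_dna, character(1))
  rc <- reverse_complement(s)
  expect_identical(nchar(rc), nchar(s))
  expect_identical(reverse_complement(rc), s)
  expect_identical(rc, oracle_revcomp(s))
})

test_that("merge_pairs finds the longest qualifying overlap", {
  mk <- function(s) data.frame(id = "p", seq = s, qual = NA)
  m <- merge_pairs(mk("AACCGGTT"), mk("CCAACC"),
                   min_overlap = 4, max_mismatch_frac = 0)
  expect_identical(m$seq, "AACCGGTTGG")
  expect_identical(m$source, "merged")

  m <- merge_pairs(mk("AAAA"), mk("TTTT"), min_overlap = 4,
                   max_mismatch_frac = 0)
  expect_identical(m$seq, "AAAA") # full-overlap identity case

  m <- merge_pairs(mk("ACGT"), mk("ACGT"), min_overlap = 3,
                   max_mismatch_frac = 0)
  expect_identical(m$seq, "ACGT") # only the full-length overlap qualifies
})

test_that("non-overlapping pairs are emitted as both unmerged mates", {
  r1 <- data.frame(id = "x", seq = "AAAAAAAA", qual = NA)
  r2 <- data.frame(id = "x", seq = "CCCCCCCC", qual = NA)
  out <- merge_pairs(r1, r2, min_overlap = 5, max_mismatch_frac = 0)
  expect_identical(out$source, c("unmerged_r1", "unmerged_r2"))
  expect_identical(out$seq, c("AAAAAAAA", "CCCCCCCC"))
})

test_that("exact merging reconstructs 1000 known fragments", {
  set.seed(42)
  n_merged <- 0L
  for (i in 1:1000) {
    L <- sample(80:110, 1)
    frag <- random_dna(L)
    r1 <- substr(frag, 1, 60)
    r2 <- reverse_complement(substr(frag, L - 59, L))
    out <- merge_pairs(data.frame(id = "f", seq = r1, qual = NA),
                       data.frame(id = "f", seq = r2, qual = NA),
                       min_overlap = 10, max_mismatch_frac = 0)
    expect_identical(out$seq, frag)
    n_merged <- n_merged + (out$source[1] == "merged")
  }
  expect_identical(n_merged, 1000L)
})

test_that("fragment count equals merged + 2 x unmerged pairs", {
  set.seed(5)
  n <- 50L
  r1 <- data.frame(id = paste0("r", 1:n),
                   seq = vapply(rep(60, n), random_dna, character(1)),
                   qual = NA)
  r2 <- data.frame(id = paste0("r", 1:n),
                   seq = vapply(rep(60, n), random_dna, character(1)),
                   qual = NA)
  out <- merge_pairs(r1, r2, min_overlap = 10, max_mismatch_frac = 0.1)
  n_merged <- sum(out$source == "merged")
  n_unmerged_pairs <- sum(out$source == "unmerged_r1")
  expect_identical(nrow(out), n_merged + 2L * n_unmerged_pairs)
  expect_identical(n_merged + n_unmerged_pairs, n)
})

test_that("overlap disagreements resolve to the higher-quality base", {
  # r1 suffix GGTT vs rc(r2) prefix GGTA: one mismatch at the last
  # overlap column; r2 carries the higher quality there
  r1 <- data.frame(id = "q", seq = "AACCGGTT", qual = "IIIIIII#")
  r2 <- data.frame(id = "q", seq = "CCTACC", qual = "IIIIII") # rc = GGTAGG
  out <- merge_pairs(r1, r2, min_overlap = 4, max_mismatch_frac = 0.25)
  expect_identical(out$source, "merged")
  expect_identical(out$seq, "AACCGGTAGG")
  # with the qualities flipped, r1 wins
  r1$qual <- "IIIIIIII"
  r2$qual <- "II#III"
  out <- merge_pairs(r1, r2, min_overlap = 4, max_mismatch_frac = 0.25)
  expect_identical(out$seq, "AACCGGTTGG")
})

test_that("length-mismatched quality raises a malformed-record error", {
  r1 <- data.frame(id = "bad_read", seq = "ACGTACGT", qual = "III")
  r2 <- data.frame(id = "bad_read", seq = "ACGTACGT", qual = "IIIIIIII")
  expect_error(merge_pairs(r1, r2), "bad_read")
})

test_that("FASTQ and FASTA round-trip losslessly, plain and gzipped", {
  dir <- withr::local_tempdir()
  set.seed(3)
  seqs <- stats::setNames(vapply(sample(50:200, 100, replace = TRUE),
                                 random_dna, character(1)),
                          paste0("contig", 1:100))
  for (ext in c("fa", "fa.gz")) {
    p <- file.path(dir, paste0("x.", ext))
    write_fasta(seqs, p)
    back <- read_fasta(p)
    expect_identical(unname(back), unname(seqs))
    expect_identical(names(back), names(seqs))
  }
  reads <- data.frame(id = paste0("r", 1:5, "/1"),
                      seq = vapply(rep(30, 5), random_dna, character(1)),
                      qual = strrep("I", 30))
  p <- file.path(dir, "x.fq.gz")
  write_fastq(reads, p)
  back <- read_fastq(p)
  expect_identical(back$seq, reads$seq)
  expect_identical(back$qual, reads$qual)
  expect_identical(back$id, reads$id)
})

test_that("mate files of unequal record count raise an error", {
  dir <- withr::local_tempdir()
  mk <- function(n) data.frame(id = paste0("r", 1:n, "/1"),
                               seq = rep("ACGTACGT", n),
                               qual = rep("IIIIIIII", n))
  write_fastq(mk(3), file.path(dir, "a.fq"))
  write_fastq(mk(2), file.path(dir, "b.fq"))
  expect_error(read_fastq_pairs(file.path(dir, "a.fq"),
                                file.path(dir, "b.fq")),
               "mate-count mismatch")
})
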