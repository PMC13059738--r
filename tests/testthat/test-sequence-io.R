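test_that("FASTA round-trips records, topology and case", {
  set.seed(3)
  recs <- lapply(1:100, function(i) {
    genome_record(sprintf("rec%03d", i), random_dna(sample(50:400, 1)),
                  topology = sample(c("linear", "circular"), 1))
  })
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, path)
  back <- read_fasta(path)
  expect_length(back, 100)
  expect_identical(vapply(back, `[[`, "", "id"), vapply(recs, `[[`, "", "id"))
  expect_identical(vapply(back, `[[`, "", "seq"), vapply(recs, `[[`, "", "seq"))
  expect_identical(vapply(back, `[[`, "", "topology"),
                   vapply(recs, `[[`, "", "topology"))
})

test_that("read normalisation: lowercase, ambiguity codes, bad characters", {
  expect_identical(genome_record("a", "acgt")$seq, "ACGT")
  expect_identical(genome_record("a", "ACRYGT")$seq, "ACNNGT")
  expect_warning(r <- genome_record("a", "ACGZ"), "non-IUPAC")
  expect_identical(r$seq, "ACGN")
  expect_error(genome_record("a", ""), "empty")
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "GGCC"), path)
  expect_error(read_fasta(path), "duplicate")
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty))
})

test_that("gc_content counts G+C over unambiguous bases", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("AATT"), 0.0)
  expect_equal(gc_content("ACGTN"), 0.5)
  expect_true(is.na(gc_content("NNNN")))
  set.seed(5)
  for (i in 1:15) {
    s <- random_dna(sample(30:300, 1), gc = runif(1))
    expect_equal(gc_content(s), gc_content(reverse_complement(s)))
  }
})

test_that("gc_skew per-window values, missing windows and cumulative track", {
  expect_equal(gc_skew("GGGG", 4)$skew, 1.0)
  expect_equal(gc_skew("GGCC", 4)$skew, 0.0)
  tr <- gc_skew("GCGGCC", window = 3, step = 3)
  expect_equal(tr$skew, c(1 / 3, -1 / 3))
  expect_equal(tr$cumulative[2], 0)
  # G+C-free window is missing, not zero, and skipped in the cumulative sum
  tr2 <- gc_skew("AAATGG", window = 3, step = 3)
  expect_true(is.na(tr2$skew[1]))
  expect_equal(tr2$cumulative, c(0, 1))
  expect_error(gc_skew("ACGT", window = 10), "window")
})

test_that("gc_skew negates under reverse complement", {
  set.seed(7)
  for (i in 1:10) {
    s <- random_dna(120, gc = runif(1, 0.3, 0.7))
    a <- gc_skew(s, window = 30, step = 30)$skew
    b <- gc_skew(reverse_complement(s), window = 30, step = 30)$skew
    expect_equal(b, -rev(a))
  }
})

test_that("gc_skew wraps across the origin on circular genomes", {
  g <- genome_record("c", "GGGGAACC", topology = "circular")
  tr <- gc_skew(g, window = 4, step = 4)
  # windows: GGGG and AACC..wrap; starts advance over the whole circle
  expect_equal(nrow(tr), 2)
  expect_equal(tr$skew[1], 1)
  expect_equal(tr$skew[2], -1)
})

test_that("codon usage counts in-frame codons additively", {
  u <- codon_usage("ATGAAATAA")
  expect_equal(unname(u[c("ATG", "AAA", "TAA")]), c(1L, 1L, 1L))
  expect_equal(sum(u), 3L)
  u0 <- codon_usage(character(0))
  expect_equal(sum(u0), 0L)
  expect_length(u0, 64L)
  a <- codon_usage("ATGAAATAA")
  b <- codon_usage("ATGGGGTAA")
  both <- codon_usage(c("ATGAAATAA", "ATGGGGTAA"))
  expect_equal(both[names(a)], a + b[names(a)])
  expect_error(codon_usage(c(bad = "ATGA")), "bad")
  set.seed(9)
  orfs <- find_orfs(random_dna(3000), 11, min_len = 90)
  expect_equal(sum(codon_usage(orfs)), sum(orfs$length) / 3)
})

test_that("GFF3 output is 1-based inclusive with a version pragma", {
  g <- genome_record("g", "ATGAAATAA")
  o <- find_orfs(g, 11, min_len = 9)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(o, path)
  lines <- readLines(path)
  expect_identical(lines[1], "##gff-version 3")
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_identical(fields[4], "1")
  expect_identical(fields[5], "9")
  expect_match(fields[9], "table_id=11")
})
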