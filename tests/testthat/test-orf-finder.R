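test_that("worked examples: stop rescue by table 25", {
  g <- genome_record("g", "ATGAAATAA")
  o <- find_orfs(g, 11, min_len = 9)
  expect_equal(nrow(o), 1)
  expect_equal(o$start, 0)
  expect_equal(o$end, 9)
  expect_identical(o$strand, "+")
  expect_identical(o$protein, "MK")

  g2 <- genome_record("g", "ATGAAATGAGGGTAA")
  o11 <- find_orfs(g2, 11, min_len = 9)
  expect_equal(c(o11$start, o11$end), c(0, 9))
  expect_identical(o11$protein, "MK")
  o25 <- find_orfs(g2, 25, min_len = 9)
  expect_equal(c(o25$start, o25$end), c(0, 15))
  expect_identical(o25$protein, "MKGG")
})

test_that("ORF sets are symmetric under reverse complement", {
  set.seed(21)
  for (i in 1:10) {
    s <- random_dna(sample(400:1500, 1), gc = runif(1, 0.3, 0.6))
    L <- nchar(s)
    a <- find_orfs(genome_record("g", s), 11, min_len = 150)
    b <- find_orfs(genome_record("g", reverse_complement(s)), 11,
                   min_len = 150)
    flip <- function(o) sort(paste(L - o$end, L - o$start,
                                   ifelse(o$strand == "+", "-", "+")))
    expect_identical(orf_keys(a), flip(b))
  }
})

test_that("find_orfs equals the brute-force start/stop enumeration oracle", {
  set.seed(33)
  for (i in 1:12) {
    s <- random_dna(sample(300:2000, 1), gc = runif(1, 0.25, 0.65))
    for (tid in c(11, 25)) {
      for (circ in c(FALSE, TRUE)) {
        g <- genome_record("g", s, if (circ) "circular" else "linear")
        expect_identical(
          orf_keys(find_orfs(g, tid, min_len = 150)),
          oracle_orfs(s, tid, min_len = 150, circular = circ),
          info = sprintf("seq %d, table %d, circular %s", i, tid, circ)
        )
      }
    }
  }
})

test_that("raising min_len never adds ORFs", {
  set.seed(4)
  s <- random_dna(3000, gc = 0.4)
  g <- genome_record("g", s)
  prev <- NULL
  for (ml in c(90L, 150L, 300L, 600L)) {
    keys <- orf_keys(find_orfs(g, 11, min_len = ml))
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("without TGA the two tables call identical ORF sets", {
  s <- paste0("ATGCCCAAACCCGGGCCCAAACCCGGGCCCAAACCCTAA",
              "CCACC", "ATGAAAGAAAAAGGAAAAGAAAAAGGAAAAGAAATAA")
  g <- genome_record("g", s)
  expect_identical(orf_keys(find_orfs(g, 11, min_len = 30)),
                   orf_keys(find_orfs(g, 25, min_len = 30)))
})

test_that("circular ORF calls are invariant under rotation", {
  set.seed(8)
  for (i in 1:6) {
    s <- random_dna(900, gc = 0.4)
    L <- nchar(s)
    base <- find_orfs(genome_record("g", s, topology = "circular"), 11,
                      min_len = 150)
    for (k in sample(1:(L - 1), 3)) {
      rot <- paste0(substr(s, k + 1, L), substr(s, 1, k))
      o <- find_orfs(genome_record("g", rot, topology = "circular"), 11,
                     min_len = 150)
      # rotate coordinates back and compare as sets
      back <- sort(paste((o$start + k) %% L, (o$start + k) %% L + o$length,
                         o$strand))
      expect_identical(back, sort(paste(base$start, base$start + base$length,
                                        base$strand)))
    }
  }
})

test_that("origin-wrapping ORFs are reported once with wrap flag", {
  s <- paste0("ATGAAATAA", "TTATTTATTTAT", "ATAAATAAATAA")
  L <- nchar(s)
  rot <- paste0(substr(s, 6, L), substr(s, 1, 5))
  o <- find_orfs(genome_record("g", rot, topology = "circular"), 11,
                 min_len = 9)
  expect_equal(nrow(o), 1)
  expect_true(o$wraps_origin)
  expect_equal(o$start, L - 5)
  expect_equal(o$length, 9)
  expect_identical(o$protein, "MK")
})

test_that("terminal repeat detection: DTR, ITR, and clean negatives", {
  x <- "GATTACAGATTACAGATTACAGCTAG"  # 26 nt
  core <- strrep("ACGTAGGCTT", 30)
  dtr <- detect_terminal_repeats(paste0(x, core, x), min_len = 20)
  expect_identical(dtr$kind, "DTR")
  expect_gte(dtr$length, 25)
  itr <- detect_terminal_repeats(paste0(x, core, reverse_complement(x)),
                                 min_len = 20)
  expect_identical(itr$kind, "ITR")
  set.seed(13)
  for (i in 1:5) {
    expect_null(detect_terminal_repeats(random_dna(10000, 0.5),
                                        min_len = 20))
  }
  expect_error(detect_terminal_repeats("ACGT", min_len = 2))
})
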