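REPEAT30 <- "GTTTCAGACGAACCCTTGTGGGATTGAAGC"  # 30 nt

test_that("array generation and spacer extraction round-trip verbatim", {
  for (k in c(0L, 1L, 4L, 6L)) {
    arr <- generate_crispr_array(REPEAT30, n_spacers = k, seed = 100 + k)
    got <- extract_spacers(arr$seq, REPEAT30, max_mismatches = 0)
    if (k == 0L) {
      # the repeat alone: below the two-occurrence minimum
      expect_identical(arr$seq, REPEAT30)
      expect_equal(nrow(got$spacers), 0)
    } else {
      expect_equal(nrow(got$repeat_occurrences), k + 1)
      expect_identical(got$spacers$seq,
                       arr$truth$seq[arr$truth$type == "spacer"])
    }
  }
})

test_that("mismatch-tolerant extraction survives a degenerate repeat copy", {
  arr <- generate_crispr_array(REPEAT30, n_spacers = 4, seed = 9)
  truth_spacers <- arr$truth$seq[arr$truth$type == "spacer"]
  # mutate one base of the middle repeat copy
  mid <- arr$truth[arr$truth$type == "repeat", ][3, ]
  s <- arr$seq
  pos <- mid$start + 10L
  old <- substr(s, pos + 1L, pos + 1L)
  substr(s, pos + 1L, pos + 1L) <- setdiff(c("A", "C", "G", "T"), old)[1]
  # at zero tolerance the degenerate copy is unrecognised: its two flanking
  # spacers fuse into one oversized segment (4 repeats -> 3 spacers)
  expect_equal(nrow(extract_spacers(s, REPEAT30, 0)$spacers), 3)
  got <- extract_spacers(s, REPEAT30, max_mismatches = 2)
  expect_identical(got$spacers$seq, truth_spacers)
})

test_that("spacer length bounds are flagged and sparse arrays rejected", {
  one <- paste0(strrep("A", 40), REPEAT30, strrep("A", 40))
  expect_equal(nrow(extract_spacers(one, REPEAT30)$spacers), 0)
  long <- paste0(REPEAT30, strrep("ACGTA", 20), REPEAT30)  # 100 nt spacer
  got <- extract_spacers(long, REPEAT30)
  expect_false(got$spacers$length_ok)
  expect_error(extract_spacers("ACGT", "ACGTACGTACGTACG"), ">= 18")
  expect_error(extract_spacers(long, REPEAT30, max_mismatches = 20),
               "max_mismatches")
})

test_that("implanted protospacers are retained per the 95/95 rule", {
  set.seed(40)
  bg <- genome_record("target", random_dna(4000, 0.4))
  sp <- random_dna(30, 0.5)
  for (case in list(list(mm = 0L, id = 100, keep = TRUE),
                    list(mm = 1L, id = 100 * 29 / 30, keep = TRUE),
                    list(mm = 2L, id = 100 * 28 / 30, keep = FALSE))) {
    imp <- implant_protospacer(bg, sp, n_mismatches = case$mm,
                               position = 1500L, strand = "+")
    m <- match_spacers(setNames(sp, "sp1"), imp$genome)
    expect_equal(nrow(m), 1)
    expect_equal(m$percent_identity, case$id, tolerance = 1e-9)
    expect_equal(m$percent_coverage, 100)
    expect_identical(m$retained, case$keep, info = paste("mm", case$mm))
    expect_equal(m$start, 1500)
    expect_identical(m$strand, "+")
    # gap-free oracle: best sliding-window Hamming distance
    d <- min(hamming_scan_oracle(imp$genome$seq, sp),
             hamming_scan_oracle(imp$genome$seq, reverse_complement(sp)))
    expect_equal(m$percent_identity, 100 * (30 - d) / 30)
  }
})

test_that("minus-strand protospacers are found and mapped back", {
  set.seed(41)
  bg <- genome_record("target", random_dna(3000, 0.4))
  sp <- random_dna(30, 0.5)
  imp <- implant_protospacer(bg, sp, n_mismatches = 0L, position = 800L,
                             strand = "-")
  m <- match_spacers(setNames(sp, "s"), imp$genome)
  expect_identical(m$strand, "-")
  expect_equal(m$start, 800)
  expect_equal(m$end, 830)
  expect_true(m$retained)
})

test_that("retention is monotone in the thresholds", {
  set.seed(42)
  bg <- genome_record("t", random_dna(2000, 0.4))
  sp <- random_dna(30, 0.5)
  imp <- implant_protospacer(bg, sp, n_mismatches = 2L, position = 700L)
  strict <- match_spacers(setNames(sp, "s"), imp$genome,
                          min_identity = 95, min_coverage = 95)
  loose <- match_spacers(setNames(sp, "s"), imp$genome,
                         min_identity = 90, min_coverage = 90)
  expect_true(all(!strict$retained | loose$retained))
  expect_true(loose$retained)
})

test_that("masking excludes a spacer's own source array from matching", {
  arr <- generate_crispr_array(REPEAT30, n_spacers = 3, seed = 77)
  src <- genome_record("src", arr$seq)
  got <- extract_spacers(src, REPEAT30)
  mask <- data.frame(target_id = "src",
                     start = min(got$repeat_occurrences$start),
                     end = max(got$repeat_occurrences$end))
  m <- match_spacers(got$spacers, src, mask = mask)
  expect_true(nrow(m) == 0 || all(!m$retained))
  # without masking, each spacer trivially matches itself
  m2 <- match_spacers(got$spacers, src)
  expect_true(all(m2$retained))
})

test_that("repeat consensus frequencies reflect column variation", {
  logo <- repeat_consensus_logo(rep(REPEAT30, 4))
  expect_equal(dim(logo$freq), c(4, 30))
  expect_true(all(apply(logo$freq, 2, max) == 1))
  variant <- REPEAT30
  substr(variant, 5, 5) <- "A"  # C -> A at position 5
  logo2 <- repeat_consensus_logo(c(REPEAT30, variant))
  expect_equal(unname(logo2$freq["A", 5]), 0.5)
  expect_equal(unname(logo2$freq["C", 5]), 0.5)
  expect_equal(sum(logo2$freq[, 5]), 1)
  expect_error(repeat_consensus_logo(character(0)), "no repeats")
})

test_that("short spacers are processed with a warning", {
  set.seed(43)
  bg <- genome_record("t", random_dna(500, 0.5))
  expect_warning(m <- match_spacers(setNames("ACGTACGTACGT", "tiny"), bg),
                 "shorter than 15")
  expect_equal(nrow(m), 1)
})
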