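test_that("genome specs validate their invariants", {
  expect_error(genome_spec(1, n_orfs = 5, n_orfs_with_internal_tga = 6),
               "<= n_orfs")
  expect_error(genome_spec(1, n_orfs = 5, table_id = 11,
                           n_orfs_with_internal_tga = 1), "infeasible")
  expect_error(genome_spec(1, n_orfs = 5, topology = "linear",
                           dtr_length = 40), "circular")
  expect_error(genome_spec(1, n_orfs = 5, orf_length_range = c(100, 600)),
               "infeasible")
  expect_error(genome_spec(1, n_orfs = 5, orf_length_range = c(301, 600)),
               "infeasible")
})

test_that("truth tables count ORFs and flags exactly", {
  res <- generate_genome(genome_spec(seed = 1, n_orfs = 5, table_id = 25,
                                     n_orfs_with_internal_tga = 2))
  expect_equal(nrow(res$truth$orfs), 5)
  expect_equal(sum(res$truth$orfs$has_internal_tga), 2)
  expect_true(all(res$truth$orfs$n_internal_tga[res$truth$orfs$has_internal_tga] >= 1))
  expect_true(all(res$truth$orfs$n_internal_tga[!res$truth$orfs$has_internal_tga] == 0))
  expect_true(all(res$truth$orfs$length %% 3 == 0))
  expect_true(all(res$truth$orfs$length >= 150))
})

test_that("identical seeds give byte-identical FASTA output", {
  spec <- genome_spec(seed = 1, n_orfs = 4, table_id = 25,
                      n_orfs_with_internal_tga = 1)
  a <- generate_genome(spec)
  b <- generate_genome(spec)
  fa <- withr::local_tempfile(fileext = ".fasta")
  fb <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(a$genome, fa)
  write_fasta(b$genome, fb)
  expect_identical(readLines(fa), readLines(fb))
  c2 <- generate_genome(genome_spec(seed = 2, n_orfs = 4, table_id = 25,
                                    n_orfs_with_internal_tga = 1))
  expect_false(identical(a$genome$seq, c2$genome$seq))
})

test_that("ORF calling recovers the truth exactly on both topologies", {
  for (topo in c("circular", "linear")) {
    for (tid in c(11L, 25L)) {
      res <- generate_genome(genome_spec(
        seed = 23, n_orfs = 6, table_id = tid,
        n_orfs_with_internal_tga = if (tid == 25L) 3L else 0L,
        topology = topo
      ))
      called <- find_orfs(res$genome, tid, min_len = 150)
      expect_identical(
        orf_keys(called),
        sort(paste(res$truth$orfs$start, res$truth$orfs$end,
                   res$truth$orfs$strand)),
        info = paste(topo, tid)
      )
      # flag fidelity: disrupted-under-11 set equals the flagged set
      if (tid == 25L) {
        ds <- disruption_statistic(called, 11)
        key <- paste(called$start, called$end)
        tkey <- paste(res$truth$orfs$start, res$truth$orfs$end)
        expect_identical(ds$disrupted[match(tkey, key)],
                         res$truth$orfs$has_internal_tga)
      }
    }
  }
})

test_that("flagged ORFs read glycine at their TGA codons under table 25", {
  res <- generate_genome(genome_spec(seed = 31, n_orfs = 4, table_id = 25,
                                     n_orfs_with_internal_tga = 4))
  called <- find_orfs(res$genome, 25, min_len = 150)
  for (i in seq_len(nrow(called))) {
    codons <- phagecode:::split_codons(called$seq[i])
    tga_at <- which(codons == "TGA")
    expect_true(length(tga_at) >= 1)
    expect_true(all(tga_at > 1 & tga_at < length(codons)))  # internal only
    aa <- strsplit(called$protein[i], "")[[1]]
    expect_true(all(aa[tga_at] == "G"))
  }
})

test_that("DTR-bearing output duplicates the circular origin", {
  res <- generate_genome(genome_spec(seed = 57, n_orfs = 4, table_id = 25,
                                     n_orfs_with_internal_tga = 1,
                                     dtr_length = 60L))
  tr <- detect_terminal_repeats(res$genome$seq, min_len = 20)
  expect_identical(tr$kind, "DTR")
  expect_gte(tr$length, 60)
  # trimming the duplicated end restores the circular core and its truth
  core <- substr(res$genome$seq, 1, nchar(res$genome$seq) - 60L)
  called <- find_orfs(genome_record("core", core, "circular"), 25)
  expect_identical(orf_keys(called),
                   sort(paste(res$truth$orfs$start, res$truth$orfs$end,
                              res$truth$orfs$strand)))
})

test_that("protospacer implanting writes the stated number of mismatches", {
  res <- generate_genome(genome_spec(seed = 3, n_orfs = 4, table_id = 25,
                                     n_orfs_with_internal_tga = 1))
  set.seed(10)
  sp <- random_dna(30, 0.5)
  imp <- implant_protospacer(res$genome, sp, n_mismatches = 1L,
                             position = 200L, strand = "+",
                             truth = res$truth)
  expect_equal(nrow(imp$truth$protospacers), 1)
  expect_equal(imp$truth$protospacers$n_mismatches, 1)
  written <- substr(imp$genome$seq, 201, 230)
  expect_equal(sum(strsplit(written, "")[[1]] != strsplit(sp, "")[[1]]), 1)
  # an implant inside an ORF is allowed but noted
  expect_match(imp$truth$protospacers$note, "overlaps")
  expect_error(implant_protospacer(res$genome, sp, position = 10^7),
               "does not fit")
})

test_that("truth bundles write FASTA, GFF3, TSV and a seed sidecar", {
  res <- generate_genome(genome_spec(seed = 8, n_orfs = 3, table_id = 25,
                                     n_orfs_with_internal_tga = 1))
  dir <- withr::local_tempdir()
  paths <- write_truth_bundle(res, dir)
  expect_true(all(file.exists(paths)))
  gff <- readLines(paths[["gff3"]])
  expect_identical(gff[1], "##gff-version 3")
  expect_equal(length(gff), 1 + 3)
  side <- jsonlite::read_json(paths[["json"]])
  expect_equal(side$seed, 8)
  expect_equal(side$n_orfs, 3)
})
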