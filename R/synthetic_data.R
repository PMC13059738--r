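# Ground-truth synthetic genomes, CRISPR arrays, protospacers and tRNA
# tables.
#
# The generator emulates the structure of a code-25 phage genome: forward-
# strand ORFs under a chosen translation table, a controlled number of which
# carry internal TGA codons (glycine under table 25, premature stops under
# table 11), separated by intergenic spacers that host no ORF of their own.
# Intergenic lengths default to the compact regime typical of tailed-phage
# genomes (~95% coding): the coding-density gain a table-25 call can show on
# a genuine table-11 genome is bounded by the non-coding fraction, so
# compactness is what makes the density-margin criterion discriminative.
# Every emitted genome satisfies an exact postcondition: calling ORFs with
# the generating table at the generator's minimum length recovers precisely
# the truth intervals, on both strands. Intergenic regions carry fixed
# "guard" motifs supplying stop codons in all six frames at the ORF
# boundaries; a deterministic repair loop then patches any residual
# spurious ORF (off-frame or reverse-strand open stretches arise in random
# coding sequence) by writing a synonymous-free stop-bearing codon pair
# into the offending frame, and re-checks until the ORF call matches the
# truth exactly.

BASES <- c("A", "C", "G", "T")

# Stops in all 3 plus frames flush against the following ORF start; no
# start codons (no G at all). TAA at offsets 1, 5, 9.
PLUS_GUARD <- "ATAAATAAATAA"
# Minus-strand stops (plus-strand TTA => minus TAA) in all 3 frames;
# no plus stops, no start codons. TTA at offsets 0, 4, 8.
MINUS_GUARD <- "TTATTTATTTAT"

GEN_MIN_ORF <- 150L

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic genome
#'
#' @param seed integer RNG seed; the same spec yields byte-identical output.
#' @param n_orfs number of ORFs.
#' @param table_id generating translation table (11 or 25).
#' @param n_orfs_with_internal_tga number of ORFs (`<= n_orfs`) carrying at
#'   least one internal in-frame TGA; requires `table_id = 25` when
#'   positive (under table 11 an internal TGA would terminate the ORF).
#' @param orf_length_range ORF length range in nt; multiples of 3, at least
#'   the generator minimum (150 nt).
#' @param intergenic_length_range intergenic length range in nt (floored at
#'   24 nt, the space the boundary guard motifs occupy).
#' @param gc_fraction GC target, applied to intergenic regions and codon
#'   wobble positions (coding constraints dominate the other positions).
#' @param topology `"circular"` (default; phage-like replicon) or
#'   `"linear"`.
#' @param dtr_length direct-terminal-repeat length (0 = none). A positive
#'   value requires circular topology; the emitted sequence then carries the
#'   first `dtr_length` nt duplicated at its end, as assemblers emit
#'   DTR-bearing contigs.
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(seed, n_orfs, table_id = 25,
                        n_orfs_with_internal_tga = 0L,
                        orf_length_range = c(300L, 1200L),
                        intergenic_length_range = c(24L, 48L),
                        gc_fraction = 0.30,
                        topology = c("circular", "linear"),
                        dtr_length = 0L) {
  topology <- match.arg(topology)
  stopifnot(n_orfs >= 1L, table_id %in% c(11L, 25L),
            gc_fraction >= 0, gc_fraction <= 1, dtr_length >= 0L)
  if (n_orfs_with_internal_tga > n_orfs) {
    stop("n_orfs_with_internal_tga must be <= n_orfs")
  }
  if (n_orfs_with_internal_tga > 0L && table_id != 25L) {
    stop("infeasible spec: internal TGA codons require table 25 ",
         "(TGA terminates translation under table 11)")
  }
  if (dtr_length > 0L && topology != "circular") {
    stop("dtr_length > 0 requires circular topology")
  }
  if (any(orf_length_range %% 3L != 0L) || orf_length_range[1] < GEN_MIN_ORF) {
    stop("infeasible spec: orf_length_range must be multiples of 3 and >= ",
         GEN_MIN_ORF, " nt")
  }
  stopifnot(orf_length_range[1] <= orf_length_range[2],
            intergenic_length_range[1] <= intergenic_length_range[2])
  structure(
    list(seed = as.integer(seed), n_orfs = as.integer(n_orfs),
         table_id = as.integer(table_id),
         n_orfs_with_internal_tga = as.integer(n_orfs_with_internal_tga),
         orf_length_range = as.integer(orf_length_range),
         intergenic_length_range = as.integer(intergenic_length_range),
         gc_fraction = gc_fraction, topology = topology,
         dtr_length = as.integer(dtr_length)),
    class = "genome_spec"
  )
}

# i.i.d. codons: first two positions uniform, wobble position GC-weighted;
# banned codons rejected.
sample_codons <- function(n, gc, banned) {
  g <- min(1, max(0, 3 * gc - 1))
  p3 <- c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)
  out <- character(0)
  while (length(out) < n) {
    m <- 2L * (n - length(out)) + 8L
    cod <- paste0(sample(BASES, m, TRUE), sample(BASES, m, TRUE),
                  sample(BASES, m, TRUE, prob = p3))
    out <- c(out, cod[!(cod %in% banned)])
  }
  out[seq_len(n)]
}

sample_bases <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(BASES, n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# One ORF: ATG + internal codons + stop. Flagged ORFs get
# max(1, Binomial(n_internal, 0.03)) internal TGAs at uniform internal
# positions (never the first or last codon), emulating code-25 genes in
# which a fraction of glycines are TGA-encoded.
build_orf <- function(len, flagged, tt, gc) {
  n_cod <- len %/% 3L
  n_int <- n_cod - 2L
  ints <- sample_codons(n_int, gc, banned = c(tt$stops, "TGA"))
  n_tga <- 0L
  if (flagged) {
    n_tga <- min(n_int, max(1L, rbinom(1L, n_int, 0.03)))
    ints[sample.int(n_int, n_tga)] <- "TGA"
  }
  stop_c <- sample(tt$stops, 1L)
  list(seq = paste0("ATG", paste(ints, collapse = ""), stop_c),
       n_tga = n_tga)
}

# Stop-bearing patches. Plus-frame stop TAA (a stop under both tables) at
# phase delta relative to the host codon grid; minus-frame stop via
# plus-strand TTA (minus TAA). Each entry: replacement codons (1 or 2).
PATCH_PLUS <- list(`1` = c("ATA", "AGC"), `2` = c("GCT", "AAC"))
PATCH_MINUS <- list(`0` = "TTA", `1` = c("ATT", "ACC"), `2` = c("ACT", "TAC"))

truth_key <- function(start, end, strand) paste(start, end, strand)

# Spurious-ORF repair: write a stop into the offending frame inside a host
# truth ORF. Returns the patched ORF codon vector, or NULL if no valid site.
patch_host_orf <- function(codons, host_start, extra, target_pos) {
  n_cod <- length(codons)
  if (extra$strand == "+") {
    phase <- extra$start %% 3L
    patches <- PATCH_PLUS
  } else {
    phase <- extra$end %% 3L
    patches <- PATCH_MINUS
  }
  # candidate host interior codon indices (1-based; exclude start & stop)
  cand <- 2:(n_cod - 1L)
  q_abs <- host_start + (cand - 1L) * 3L       # absolute codon starts
  delta <- (phase - q_abs) %% 3L
  need_pair <- delta != 0L
  ok <- vapply(seq_along(cand), function(i) {
    key <- as.character(delta[i])
    if (!key %in% names(patches)) return(FALSE)
    idx <- cand[i]
    if (need_pair[i] && idx + 1L > n_cod - 1L) return(FALSE)
    if (codons[idx] == "TGA") return(FALSE)
    if (need_pair[i] && codons[idx + 1L] == "TGA") return(FALSE)
    p <- q_abs[i] + delta[i]                   # stop trinucleotide position
    # stop must fall strictly inside the spurious ORF, clear of its ends
    p >= extra$start + 3L && p + 3L <= extra$end - 3L
  }, logical(1))
  if (!any(ok)) return(NULL)
  # a random site (seeded upstream) rather than a fixed one: deterministic
  # placement can oscillate when two overlapping spurious frames keep
  # overwriting each other's repair stops
  cand_ok <- which(ok)
  mid <- (extra$start + extra$end) %/% 2L
  w <- 1 / (1 + abs(q_abs[cand_ok] - mid) / 30)
  pick <- if (length(cand_ok) == 1L) cand_ok else
    sample(cand_ok, 1L, prob = w)
  idx <- cand[pick]
  repl <- patches[[as.character(delta[pick])]]
  codons[idx:(idx + length(repl) - 1L)] <- repl
  codons
}

#' Generate a synthetic genome with ground truth
#'
#' Emits a genome that contains exactly `spec$n_orfs` forward-strand ORFs
#' under `spec$table_id` at the generator's minimum length (150 nt), of
#' which exactly `spec$n_orfs_with_internal_tga` carry at least one internal
#' TGA, and nothing else: no spurious ORF survives on either strand under
#' the generating table, and intergenic regions host no ORF under either
#' candidate table (11 or 25). Identical seeds yield byte-identical output.
#'
#' @param spec a [genome_spec()].
#' @param max_repair maximum repair iterations before declaring the spec
#'   infeasible.
#' @return list: `genome` (a [genome_record()]) and `truth` (class
#'   `truth_table`: `orfs` data.frame with `orf_id`, `start`, `end`,
#'   `strand`, `length`, `has_internal_tga`, `n_internal_tga`;
#'   `intergenic` data.frame; `spec`; empty `protospacers`).
#' @export
generate_genome <- function(spec, max_repair = 80L) {
  stopifnot(inherits(spec, "genome_spec"))
  tt <- translation_table(spec$table_id)
  other <- translation_table(if (spec$table_id == 25L) 11L else 25L)
  with_seed(spec$seed, {
    flags <- logical(spec$n_orfs)
    if (spec$n_orfs_with_internal_tga > 0L) {
      flags[sample.int(spec$n_orfs, spec$n_orfs_with_internal_tga)] <- TRUE
    }
    lr <- spec$orf_length_range
    lens <- 3L * sample(seq.int(lr[1] %/% 3L, lr[2] %/% 3L),
                        spec$n_orfs, replace = TRUE)
    orfs <- lapply(seq_len(spec$n_orfs), function(i) {
      build_orf(lens[i], flags[i], tt, spec$gc_fraction)
    })
    orf_codons <- lapply(orfs, function(o) split_codons(o$seq))
    ir <- spec$intergenic_length_range
    ig_lens <- pmax(24L, sample(seq.int(ir[1], ir[2]),
                                spec$n_orfs, replace = TRUE))
    ig_cores <- vapply(ig_lens - 24L, sample_bases, character(1),
                       gc = spec$gc_fraction)

    assemble <- function() {
      pieces <- character(0)
      starts <- integer(spec$n_orfs)
      ig_iv <- matrix(0L, nrow = spec$n_orfs, ncol = 2L)
      pos <- 0L
      for (i in seq_len(spec$n_orfs)) {
        starts[i] <- pos
        oseq <- paste(orf_codons[[i]], collapse = "")
        pieces <- c(pieces, oseq)
        pos <- pos + nchar(oseq)
        ig <- paste0(MINUS_GUARD, ig_cores[i], PLUS_GUARD)
        ig_iv[i, ] <- c(pos, pos + nchar(ig))
        pieces <- c(pieces, ig)
        pos <- pos + nchar(ig)
      }
      list(seq = paste(pieces, collapse = ""), starts = starts, ig_iv = ig_iv)
    }

    # Linear genomes need an upstream guard for the first ORF: prepend a
    # plus guard (kept out of the truth intergenic bookkeeping).
    prefix <- if (spec$topology == "linear") PLUS_GUARD else ""
    npre <- nchar(prefix)

    for (iter in seq_len(max_repair)) {
      asm <- assemble()
      g <- genome_record("synthetic", paste0(prefix, asm$seq), spec$topology)
      t_start <- asm$starts + npre
      t_end <- t_start + lens
      tkey <- truth_key(t_start, t_end, "+")
      called <- find_orfs(g, tt, min_len = GEN_MIN_ORF)
      ckey <- truth_key(called$start, called$end, called$strand)
      extras <- called[!(ckey %in% tkey), , drop = FALSE]
      missing <- setdiff(tkey, ckey)
      ig_iv <- cbind(asm$ig_iv[, 1] + npre, asm$ig_iv[, 2] + npre)
      other_called <- find_orfs(g, other, min_len = GEN_MIN_ORF)
      in_ig <- vapply(seq_len(nrow(other_called)), function(i) {
        any(other_called$start[i] >= ig_iv[, 1] &
              other_called$end[i] <= ig_iv[, 2])
      }, logical(1))
      extras <- rbind(extras, other_called[in_ig, , drop = FALSE])
      if (nrow(extras) == 0L && length(missing) == 0L) {
        truth <- structure(list(
          orfs = data.frame(
            orf_id = sprintf("truth_orf%03d", seq_len(spec$n_orfs)),
            start = t_start, end = t_end, strand = "+",
            length = lens,
            has_internal_tga = flags,
            n_internal_tga = vapply(orfs, `[[`, integer(1), "n_tga"),
            stringsAsFactors = FALSE
          ),
          intergenic = data.frame(start = ig_iv[, 1], end = ig_iv[, 2]),
          protospacers = data.frame(
            start = integer(0), end = integer(0), strand = character(0),
            n_mismatches = integer(0), note = character(0)
          ),
          spec = spec
        ), class = "truth_table")
        gs <- g$seq
        if (spec$dtr_length > 0L) {
          gs <- paste0(gs, substr(gs, 1L, spec$dtr_length))
        }
        out_g <- genome_record("synthetic", gs, spec$topology,
                               description = sprintf("seed=%d table=%d",
                                                     spec$seed, spec$table_id))
        return(list(genome = out_g, truth = truth))
      }
      # repair pass. Extras wrapping the circular origin have end > L;
      # origin-shifted copies of every host ORF / intergenic interval keep
      # the phase arithmetic consistent on the unwrapped coordinate line.
      L <- genome_length(g)
      t_start2 <- c(t_start, t_start + L)
      t_end2 <- c(t_end, t_end + L)
      ig_iv2 <- rbind(ig_iv, ig_iv + L)
      for (e in seq_len(nrow(extras))) {
        extra <- extras[e, ]
        ov <- pmin(extra$end, t_end2) - pmax(extra$start, t_start2)
        host <- which.max(ov)
        host_idx <- (host - 1L) %% spec$n_orfs + 1L
        patched <- NULL
        if (ov[host] >= 12L) {
          patched <- patch_host_orf(orf_codons[[host_idx]], t_start2[host],
                                    extra, NULL)
        }
        if (!is.null(patched)) {
          orf_codons[[host_idx]] <- patched
        } else {
          # spurious ORF lives (mostly) in intergenic space: redraw cores
          ig_hit <- which(ig_iv2[, 2] > extra$start &
                            ig_iv2[, 1] < extra$end)
          ig_hit <- unique((ig_hit - 1L) %% spec$n_orfs + 1L)
          if (!length(ig_hit)) ig_hit <- seq_len(spec$n_orfs)
          for (k in ig_hit) {
            ig_cores[k] <- sample_bases(nchar(ig_cores[k]), spec$gc_fraction)
          }
        }
      }
      if (length(missing) && nrow(extras) == 0L) {
        # should not happen with guards in place; force a reshuffle
        ig_cores[] <- vapply(nchar(ig_cores), sample_bases, character(1),
                             gc = spec$gc_fraction)
      }
    }
    stop("infeasible spec: genome failed to validate after ", max_repair,
         " repair iterations")
  })
}

#' Generate a CRISPR array
#'
#' `repeat . (spacer_i . repeat) ^ n_spacers`: `n_spacers + 1` repeat
#' copies interleaved with mutually distinct random spacers, none of which
#' contains the repeat; the emitted sequence is validated to contain exactly
#' `n_spacers + 1` exact repeat occurrences.
#'
#' @param repeat_seq direct-repeat sequence (`>= 18` nt).
#' @param n_spacers number of spacers (`>= 0`).
#' @param spacer_length spacer length in nt (default 30).
#' @param seed RNG seed.
#' @param max_tries resampling attempts before giving up.
#' @return list: `seq` (the array), `truth` (data.frame of elements:
#'   `type` repeat/spacer, `start`, `end`, `seq`).
#' @export
generate_crispr_array <- function(repeat_seq, n_spacers, spacer_length = 30L,
                                  seed = 1L, max_tries = 50L) {
  stopifnot(n_spacers >= 0L)
  repeat_seq <- toupper(repeat_seq)
  if (nchar(repeat_seq) < 18L) stop("repeat must be >= 18 nt")
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      spacers <- vapply(seq_len(n_spacers), function(i) {
        sample_bases(spacer_length, 0.5)
      }, character(1))
      if (n_spacers > 0L &&
          (anyDuplicated(spacers) ||
             any(vapply(spacers, grepl, logical(1), x = repeat_seq,
                        fixed = TRUE)) ||
             any(grepl(repeat_seq, spacers, fixed = TRUE)))) next
      parts <- repeat_seq
      for (sp in spacers) parts <- c(parts, sp, repeat_seq)
      seq <- paste(parts, collapse = "")
      occ <- which(hamming_scan(seq, repeat_seq) == 0L)
      if (length(occ) != n_spacers + 1L) next
      lens <- nchar(parts)
      ends <- cumsum(lens)
      starts <- ends - lens
      truth <- data.frame(
        type = rep(c("repeat", "spacer"), length.out = length(parts)),
        start = starts, end = ends, seq = parts,
        stringsAsFactors = FALSE
      )
      return(list(seq = seq, truth = truth))
    }
    stop("failed to generate a collision-free CRISPR array after ",
         max_tries, " tries")
  })
}

#' Implant a protospacer into a genome
#'
#' Writes a copy of `spacer` carrying exactly `n_mismatches` substitutions
#' into the genome at `position` (0-based) on the given strand.
#' Substitution sites are drawn from interior spacer positions (at least
#' 5 nt from either end), so that a full-length local alignment — and the
#' identity arithmetic `(length - n_mismatches) / length` — is preserved.
#'
#' @param genome a [genome_record()].
#' @param spacer spacer sequence.
#' @param n_mismatches substitution count (`<=` available interior sites).
#' @param position 0-based target position; `position + nchar(spacer)` must
#'   not exceed the genome length.
#' @param strand `"+"` or `"-"` (the reverse complement is implanted).
#' @param truth optional `truth_table` to update; overlap with a truth ORF
#'   boundary is allowed but noted.
#' @return list: `genome` (modified record), `truth` (updated or a fresh
#'   implant data.frame), `implanted` (the written sequence).
#' @export
implant_protospacer <- function(genome, spacer, n_mismatches = 0L,
                                position = 0L, strand = c("+", "-"),
                                truth = NULL) {
  strand <- match.arg(strand)
  spacer <- toupper(spacer)
  len <- nchar(spacer)
  L <- genome_length(genome)
  if (position < 0L || position + len > L) {
    stop("protospacer does not fit: position + spacer length exceeds genome")
  }
  if (n_mismatches > len) stop("n_mismatches exceeds spacer length")
  variant <- spacer
  if (n_mismatches > 0L) {
    interior <- 6L:(len - 5L)
    if (length(interior) < n_mismatches) {
      stop("spacer too short for ", n_mismatches, " interior substitutions")
    }
    sites <- sample(interior, n_mismatches)
    chars <- strsplit(variant, "", fixed = TRUE)[[1L]]
    for (s in sites) chars[s] <- sample(setdiff(BASES, chars[s]), 1L)
    variant <- paste(chars, collapse = "")
  }
  written <- if (strand == "+") variant else reverse_complement(variant)
  seq <- genome$seq
  substr(seq, position + 1L, position + len) <- written
  out <- genome
  out$seq <- seq
  note <- ""
  if (!is.null(truth) && nrow(truth$orfs)) {
    hit <- truth$orfs$end > position & truth$orfs$start < position + len
    if (any(hit)) {
      note <- paste("overlaps", paste(truth$orfs$orf_id[hit], collapse = ","))
    }
  }
  row <- data.frame(start = position, end = position + len, strand = strand,
                    n_mismatches = n_mismatches, note = note,
                    stringsAsFactors = FALSE)
  if (!is.null(truth)) {
    truth$protospacers <- rbind(truth$protospacers, row)
  } else {
    truth <- row
  }
  list(genome = out, truth = truth, implanted = written)
}

#' Generate a tRNA annotation table
#'
#' One record per anticodon with synthetic coordinates and the isotype
#' implied by the decoded codon under table 11; anticodons decoding a stop
#' codon (suppressors) are labelled by the table-25 meaning where one
#' exists (TGA -> Gly), otherwise `Sup`.
#'
#' @param anticodons character vector of 3-nt anticodons over `{A,C,G,T}`.
#' @param seed RNG seed (reserved; coordinates are deterministic).
#' @return data.frame `name`, `begin`, `end`, `isotype`, `anticodon`.
#' @export
generate_trna_table <- function(anticodons, seed = 1L) {
  if (length(anticodons) == 0L) {
    return(data.frame(name = character(0), begin = integer(0),
                      end = integer(0), isotype = character(0),
                      anticodon = character(0)))
  }
  anticodons <- toupper(anticodons)
  codons <- vapply(anticodons, decode_anticodon, character(1),
                   USE.NAMES = FALSE)
  isotypes <- vapply(codons, isotype_of, character(1), USE.NAMES = FALSE)
  begin <- 100L + (seq_along(anticodons) - 1L) * 100L
  data.frame(
    name = sprintf("tRNA-%s-%s", isotypes, anticodons),
    begin = begin, end = begin + 75L,
    isotype = isotypes, anticodon = anticodons,
    stringsAsFactors = FALSE
  )
}

#' Write generator truth to disk
#'
#' FASTA (60-column), truth GFF3 (1-based inclusive), truth TSV, and a JSON
#' sidecar recording the seed and spec.
#'
#' @param result list from [generate_genome()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
write_truth_bundle <- function(result, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, paste0(prefix, ".fasta")),
    gff3 = file.path(dir, paste0(prefix, "_truth.gff3")),
    tsv = file.path(dir, paste0(prefix, "_truth.tsv")),
    json = file.path(dir, paste0(prefix, "_spec.json"))
  )
  write_fasta(result$genome, paths[["fasta"]])
  orfs <- result$truth$orfs
  con <- file(paths[["gff3"]], "w")
  writeLines("##gff-version 3", con)
  if (nrow(orfs)) {
    writeLines(sprintf(
      "%s\tphagecode_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;has_internal_tga=%s",
      result$genome$id, orfs$start + 1L, orfs$end, orfs$strand, orfs$orf_id,
      tolower(orfs$has_internal_tga)
    ), con)
  }
  close(con)
  write.table(orfs, paths[["tsv"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(unclass(result$truth$spec), paths[["json"]],
                       auto_unbox = TRUE)
  invisible(paths)
}
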