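# CRISPR array reconstruction and spacer-protospacer matching.
#
# Arrays are reconstructed from a supplied repeat sequence (de novo repeat
# discovery is an external problem): repeat occurrences are found by a
# mismatch-tolerant scan and the intervening segments are the spacers.
# Spacer hits against target genomes follow the BLASTn-style retention
# rule: >= 95% identity and >= 95% coverage.

# Hamming distance of `pattern` against every window of `seq`.
hamming_scan <- function(seq, pattern) {
  M <- nchar(seq)
  r <- nchar(pattern)
  if (M < r) return(integer(0))
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  p <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  n_win <- M - r + 1L
  d <- integer(n_win)
  for (j in seq_len(r)) d <- d + (s[j:(j + n_win - 1L)] != p[j])
  d
}

#' Extract spacers from a CRISPR array
#'
#' Finds all non-overlapping occurrences of `repeat_seq` within Hamming
#' distance `max_mismatches` (greedy left-to-right) and returns the
#' inter-repeat segments as spacers. A well-formed array of `R` repeats
#' yields `R - 1` spacers. Fewer than 2 repeat occurrences reject the array
#' (empty result). Spacers with length outside `[15, 60]` nt are flagged,
#' not dropped.
#'
#' @param sequence array-bearing nucleotide string or [genome_record()].
#' @param repeat_seq direct-repeat sequence (`>= 18` nt).
#' @param max_mismatches per-occurrence mismatch tolerance
#'   (`<= floor(repeat length / 6)`).
#' @return list of class `crispr_array`: `repeat_consensus`,
#'   `repeat_occurrences` (data.frame `start`, `end`, `mismatches`; 0-based
#'   half-open), `spacers` (data.frame `spacer_id`, `start`, `end`, `seq`,
#'   `length_ok`). Empty occurrence/spacer tables when no array is found.
#' @export
extract_spacers <- function(sequence, repeat_seq, max_mismatches = 0L) {
  genome_id <- "seq"
  if (inherits(sequence, "genome_record")) {
    genome_id <- sequence$id
    sequence <- sequence$seq
  }
  r <- nchar(repeat_seq)
  if (r < 18L) stop("repeat must be >= 18 nt")
  if (max_mismatches > r %/% 6L) {
    stop("max_mismatches must be <= floor(repeat length / 6) = ", r %/% 6L)
  }
  d <- hamming_scan(toupper(sequence), toupper(repeat_seq))
  hits <- which(d <= max_mismatches)           # 1-based window starts
  occ <- integer(0)
  last_end <- 0L
  for (h in hits) {                            # greedy, non-overlapping
    if (h > last_end) {
      occ <- c(occ, h)
      last_end <- h + r - 1L
    }
  }
  empty <- list(
    genome_id = genome_id, repeat_consensus = toupper(repeat_seq),
    repeat_occurrences = data.frame(start = integer(0), end = integer(0),
                                    mismatches = integer(0),
                                    seq = character(0)),
    spacers = data.frame(spacer_id = character(0), start = integer(0),
                         end = integer(0), seq = character(0),
                         length_ok = logical(0))
  )
  class(empty) <- "crispr_array"
  if (length(occ) < 2L) return(empty)
  occs <- data.frame(start = occ - 1L, end = occ - 1L + r,
                     mismatches = d[occ],
                     seq = substring(sequence, occ, occ + r - 1L))
  sp_start <- occs$end[-nrow(occs)]
  sp_end <- occs$start[-1L]
  keep <- sp_end > sp_start
  sp_start <- sp_start[keep]
  sp_end <- sp_end[keep]
  spacers <- data.frame(
    spacer_id = sprintf("%s_spacer%02d", genome_id, seq_along(sp_start)),
    start = sp_start, end = sp_end,
    seq = substring(sequence, sp_start + 1L, sp_end),
    length_ok = (sp_end - sp_start) >= 15L & (sp_end - sp_start) <= 60L
  )
  out <- empty
  out$repeat_occurrences <- occs
  out$spacers <- spacers
  out
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf("<crispr_array '%s'> %d repeat occurrence(s), %d spacer(s)\n",
              x$genome_id, nrow(x$repeat_occurrences), nrow(x$spacers)))
  invisible(x)
}

spacer_substitution_matrix <- function() {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-3, 5, 5, dimnames = list(letters, letters))
  diag(m) <- 2
  m["N", ] <- -6
  m[, "N"] <- -6
  m
}

align_one <- function(spacer, target_seq) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(spacer), Biostrings::DNAString(target_seq),
    type = "local",
    substitutionMatrix = spacer_substitution_matrix(),
    gapOpening = 5, gapExtension = 2
  )
  gp <- as.character(Biostrings::alignedPattern(aln))
  cols <- nchar(gp)
  if (cols == 0L) return(NULL)
  n_match <- Biostrings::nmatch(aln)
  aligned_spacer <- cols - lengths(regmatches(gp, gregexpr("-", gp, fixed = TRUE)))
  sub_rng <- Biostrings::subject(aln)
  list(
    score = Biostrings::score(aln),
    start = Biostrings::start(sub_rng) - 1L,      # 0-based half-open
    end = Biostrings::end(sub_rng),
    identity = 100 * n_match / cols,
    coverage = 100 * aligned_spacer / nchar(spacer)
  )
}

#' Match CRISPR spacers against target genomes
#'
#' For each spacer, aligns against both strands of every target with a
#' local, BLASTn-like scoring scheme (match 2, mismatch -3, gap open 5, gap
#' extend 2) and reports the best hit per spacer-target pair. Percent
#' identity is `100 * matches / alignment columns` (gap columns included,
#' the BLAST convention); percent coverage is
#' `100 * aligned spacer positions / spacer length`. A hit is retained iff
#' identity >= `min_identity` and coverage >= `min_coverage` (default the
#' >= 95% / >= 95% rule). Ties break by `(target_id, leftmost coordinate,
#' "+" strand first)`.
#'
#' @param spacers character vector of spacer sequences (named, or names are
#'   generated), or the `spacers` data.frame of a [extract_spacers()] array.
#' @param targets list of [genome_record()] objects (or one).
#' @param min_identity,min_coverage retention thresholds in percent.
#' @param mask optional data.frame (`target_id`, `start`, `end`; 0-based
#'   half-open) of regions to exclude — e.g. the spacer's own source array;
#'   masked regions are replaced by `N` before alignment.
#' @return data.frame: `spacer_id`, `target_id`, `start`, `end` (0-based
#'   half-open on the forward strand), `strand`, `percent_identity`,
#'   `percent_coverage`, `retained`. One row per spacer-target pair with an
#'   alignable hit.
#' @export
match_spacers <- function(spacers, targets, min_identity = 95,
                          min_coverage = 95, mask = NULL) {
  if (is.data.frame(spacers)) {
    spacers <- setNames(spacers$seq, spacers$spacer_id)
  }
  if (length(spacers) == 0L) stop("no spacers supplied")
  if (is.null(names(spacers))) {
    names(spacers) <- sprintf("spacer%02d", seq_along(spacers))
  }
  if (inherits(targets, "genome_record")) targets <- list(targets)
  short <- nchar(spacers) < 15L
  if (any(short)) {
    warning(sum(short), " spacer(s) shorter than 15 nt; processed anyway")
  }
  rows <- list()
  for (si in seq_along(spacers)) {
    sp <- toupper(spacers[[si]])
    cands <- list()
    for (tg in targets) {
      tseq <- tg$seq
      if (!is.null(mask)) {
        for (mi in which(mask$target_id == tg$id)) {
          a <- mask$start[mi]
          b <- mask$end[mi]
          substr(tseq, a + 1L, b) <- strrep("N", b - a)
        }
      }
      Lt <- nchar(tseq)
      for (strand in c("+", "-")) {
        hit <- align_one(sp, if (strand == "+") tseq else reverse_complement(tseq))
        if (is.null(hit)) next
        if (strand == "-") {
          tmp <- hit
          hit$start <- Lt - tmp$end
          hit$end <- Lt - tmp$start
        }
        cands[[length(cands) + 1L]] <- c(
          list(target_id = tg$id, strand = strand), hit
        )
      }
    }
    if (!length(cands)) next
    # best per target across strands; deterministic tie-break
    by_target <- split(cands, vapply(cands, `[[`, character(1), "target_id"))
    for (tg_id in sort(names(by_target))) {
      cs <- by_target[[tg_id]]
      scores <- vapply(cs, `[[`, numeric(1), "score")
      best <- cs[scores == max(scores)]
      ord <- order(vapply(best, `[[`, numeric(1), "start"),
                   vapply(best, `[[`, character(1), "strand"))
      b <- best[[ord[1L]]]
      rows[[length(rows) + 1L]] <- data.frame(
        spacer_id = names(spacers)[si], target_id = b$target_id,
        start = b$start, end = b$end, strand = b$strand,
        percent_identity = b$identity, percent_coverage = b$coverage,
        retained = b$identity >= min_identity & b$coverage >= min_coverage
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(spacer_id = character(0), target_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), percent_identity = numeric(0),
                      percent_coverage = numeric(0), retained = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Positional base frequencies of CRISPR repeats
#'
#' Builds the per-position base-frequency table (the numbers behind a
#' sequence logo) from the repeat occurrences of one or more arrays.
#' Repeats longer than the consensus length are trimmed and shorter ones
#' padded; padded positions do not enter the denominator, so each column's
#' frequencies sum to 1 over the bases observed there.
#'
#' @param arrays list of `crispr_array` objects (or one), or a character
#'   vector of repeat sequences.
#' @return list: `freq` (4 x L matrix, rows A/C/G/T), `n_repeats`,
#'   `consensus_length`, `n_padded`, `n_trimmed`.
#' @export
repeat_consensus_logo <- function(arrays) {
  reps <- if (is.character(arrays)) {
    arrays
  } else {
    if (inherits(arrays, "crispr_array")) arrays <- list(arrays)
    unlist(lapply(arrays, function(a) a$repeat_occurrences$seq))
  }
  reps <- toupper(reps)
  if (!length(reps)) stop("no repeats supplied")
  lens <- nchar(reps)
  L <- as.integer(stats::median(lens))
  n_trimmed <- sum(lens > L)
  n_padded <- sum(lens < L)
  mat <- matrix(0, nrow = 4, ncol = L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (rp in reps) {
    chars <- strsplit(substr(rp, 1L, L), "", fixed = TRUE)[[1L]]
    for (i in seq_along(chars)) {
      if (chars[i] %in% rownames(mat)) mat[chars[i], i] <- mat[chars[i], i] + 1
    }
  }
  totals <- colSums(mat)
  freq <- sweep(mat, 2, ifelse(totals == 0, 1, totals), "/")
  list(freq = freq, n_repeats = length(reps), consensus_length = L,
       n_padded = n_padded, n_trimmed = n_trimmed)
}

#' Write a spacer-match table as TSV
#'
#' Columns: spacer, target, start, end, strand, identity, coverage,
#' retained.
#'
#' @param matches data.frame from [match_spacers()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spacer_matches <- function(matches, path) {
  write.table(matches, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
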