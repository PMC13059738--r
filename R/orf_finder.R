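# ORF enumeration on linear and circular sequences.
#
# Semantics: an ORF is the maximal open reading frame of a stop-bounded
# segment — from the FIRST in-frame start codon after the previous in-frame
# stop, through the terminating stop codon (included in the interval and the
# length, excluded from the protein). One ORF per segment; segments lacking a
# start codon, or whose maximal ORF is shorter than min_len, yield nothing.
# Codons containing N translate to X and never terminate an ORF.
#
# Circular genomes are scanned on the sequence tripled: every candidate whose
# start falls in the middle copy has >= L nt of genuine upstream and
# downstream context, so the first-start rule and the terminating stop are
# decided with full circular information for any ORF of length <= L. Each
# circular codon position maps to exactly one middle-copy position, so no
# deduplication is needed. Candidates longer than L (a near-stop-free frame
# reading all the way around) are dropped.

# Scan one linear strand string; returns 0-based (start, len, frame) triples.
# In `circular_mode`, `s` is the tripled sequence of a circular genome of
# length L and only candidates starting in [L, 2L) with a genuine upstream
# stop are kept.
scan_strand <- function(s, tt, min_len, start_codons, circular_mode = FALSE,
                        L = nchar(s)) {
  n <- nchar(s)
  res <- list()
  for (f in 0:2) {
    n_cod <- (n - f) %/% 3L
    if (n_cod < 2L) next
    at <- f + 3L * (0:(n_cod - 1L))            # 0-based codon start positions
    codons <- substring(s, at + 1L, at + 3L)
    is_stop <- codons %in% tt$stops
    is_start <- codons %in% start_codons
    stop_idx <- which(is_stop)
    if (!length(stop_idx)) next
    prev <- c(0L, stop_idx[-length(stop_idx)])  # codon index of previous stop
    for (k in seq_along(stop_idx)) {
      j <- stop_idx[k]
      lo <- prev[k] + 1L
      if (lo > j - 1L) next
      hit <- which(is_start[lo:(j - 1L)])
      if (!length(hit)) next
      i <- lo + hit[1L] - 1L
      len <- (j - i + 1L) * 3L
      if (len < min_len) next
      st <- at[i]
      if (circular_mode) {
        if (st < L || st >= 2L * L) next
        if (prev[k] == 0L) next                  # no verified upstream stop
        if (len > L) next
      }
      res[[length(res) + 1L]] <- c(st, len, f)
    }
  }
  res
}

orf_row <- function(genome_id, start, len, strand, frame, table_id, L,
                    circular, seq, tt) {
  wraps <- circular && (start + len > L)
  protein_nt <- substr(seq, 1L, len - 3L)
  data.frame(
    genome_id = genome_id,
    start = start, end = start + len, length = len,
    strand = strand, frame = frame,
    table_id = table_id, wraps_origin = wraps,
    seq = seq,
    protein = translate_seq(protein_nt, tt),
    stringsAsFactors = FALSE
  )
}

#' Predict open reading frames
#'
#' Enumerates ORFs on both strands of a linear or circular genome under a
#' given translation table: for every stop-bounded reading-frame segment, the
#' maximal ORF from the first in-frame start codon through the terminating
#' stop, if at least `min_len` nt. Coordinates are 0-based half-open on the
#' forward strand; ORFs wrapping the origin of a circular genome are reported
#' once, at their canonical start in `[0, L)`, with `end > L` and
#' `wraps_origin = TRUE`.
#'
#' @param genome a [genome_record()] (a plain string is treated as a linear
#'   genome).
#' @param table a `translation_table` or NCBI table number (e.g. 11 or 25).
#' @param min_len minimum ORF length in nt, stop codon included; must be
#'   `>= 3` and divisible by 3. Default 150, a common prokaryotic gene-caller
#'   convention.
#' @param start_codons start-codon set; defaults to the table's
#'   (`ATG`/`GTG`/`TTG` unless overridden in [translation_table()]).
#' @return data.frame with one row per ORF: `orf_id`, `genome_id`, `start`,
#'   `end`, `length`, `strand`, `frame` (start offset mod 3 on the reading
#'   strand), `table_id`, `wraps_origin`, `seq` (coding strand, stop
#'   included), `protein` (terminal stop excluded). Sorted by
#'   `(start, strand)`.
#' @examples
#' g <- genome_record("g", "ATGAAATGAGGGTAA")
#' find_orfs(g, 11, min_len = 9)$protein # "MK"
#' find_orfs(g, 25, min_len = 9)$protein # "MKGG"
#' @export
find_orfs <- function(genome, table, min_len = 150L, start_codons = NULL) {
  if (!inherits(genome, "genome_record")) {
    genome <- genome_record("seq", genome, "linear")
  }
  tt <- as_translation_table(table)
  if (is.null(start_codons)) start_codons <- tt$starts
  if (min_len < 3L || min_len %% 3L != 0L) {
    stop("min_len must be >= 3 and divisible by 3")
  }
  L <- genome_length(genome)
  circular <- genome$topology == "circular"
  if (circular && L < 3L) stop("circular genome shorter than 3 nt")

  fwd <- if (circular) strrep(genome$seq, 3L) else genome$seq
  rev <- reverse_complement(fwd)
  n_fwd <- nchar(fwd)

  rows <- list()
  for (hit in scan_strand(fwd, tt, min_len, start_codons, circular, L)) {
    st <- hit[1L]; len <- hit[2L]
    seq <- substr(fwd, st + 1L, st + len)
    canon <- if (circular) st %% L else st
    rows[[length(rows) + 1L]] <-
      orf_row(genome$id, canon, len, "+", canon %% 3L, tt$table_id, L,
              circular, seq, tt)
  }
  for (hit in scan_strand(rev, tt, min_len, start_codons, circular, L)) {
    st <- hit[1L]; len <- hit[2L]
    seq <- substr(rev, st + 1L, st + len)
    fwd_start <- n_fwd - st - len              # left end on forward strand
    canon <- if (circular) fwd_start %% L else fwd_start
    rows[[length(rows) + 1L]] <-
      orf_row(genome$id, canon, len, "-", st %% 3L, tt$table_id, L,
              circular, seq, tt)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    orf_row("x", 0L, 3L, "+", 0L, tt$table_id, 3L, FALSE, "TAA", tt)[0L, ]
  out <- out[order(out$start, out$strand, out$end), , drop = FALSE]
  out <- cbind(orf_id = if (nrow(out)) sprintf("%s_orf%03d", out$genome_id,
                                               seq_len(nrow(out))) else character(0),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Detect terminal repeats
#'
#' Finds the longest exact terminal repeat of a linear sequence: a direct
#' terminal repeat (DTR; prefix equals suffix) or an inverted terminal
#' repeat (ITR; prefix equals the reverse complement of the suffix), both
#' signatures of complete phage genome assemblies. DTR is preferred when
#' both exist at the same length.
#'
#' @param seq nucleotide string or [genome_record()].
#' @param min_len minimum repeat length in nt (default 20, `>= 10`).
#' @return `NULL` if no terminal repeat of at least `min_len` exists,
#'   otherwise a list with `kind` (`"DTR"` or `"ITR"`), `length`, `left`
#'   and `right` 0-based half-open coordinate pairs.
#' @export
detect_terminal_repeats <- function(seq, min_len = 20L) {
  if (inherits(seq, "genome_record")) seq <- seq$seq
  stopifnot(min_len >= 10L)
  L <- nchar(seq)
  kmax <- L %/% 2L
  if (kmax < min_len) return(NULL)
  rc <- reverse_complement(seq)
  for (k in kmax:min_len) {
    pre <- substr(seq, 1L, k)
    if (pre == substr(seq, L - k + 1L, L)) {
      return(list(kind = "DTR", length = k,
                  left = c(0L, k), right = c(L - k, L)))
    }
    # suffix reverse-complemented == prefix of rc's ... rc suffix of length k
    if (pre == substr(rc, 1L, k)) {
      return(list(kind = "ITR", length = k,
                  left = c(0L, k), right = c(L - k, L)))
    }
  }
  NULL
}
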