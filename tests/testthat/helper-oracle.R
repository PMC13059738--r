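# Independent brute-force ORF oracle: enumerate every start-codon position,
# walk codon-by-codon to the terminating stop, and keep a candidate only if
# walking BACKWARDS from the start meets a stop before any other start (the
# maximality / first-start-after-previous-stop rule). Deliberately
# position-by-position and modular, sharing no code with the package's
# segment-based scanner.

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

oracle_strand <- function(s, stops, starts, min_len, circular) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  codon_at <- function(p) {
    idx <- if (circular) (p + 0:2) %% L + 1L else p + 1:3
    paste(chars[idx], collapse = "")
  }
  res <- list()
  p_max <- if (circular) L - 1L else L - 3L
  if (p_max < 0L) return(res)
  for (p in 0:p_max) {
    if (!(codon_at(p) %in% starts)) next
    # forward: find the terminating stop (ORFs longer than L are dropped)
    q <- p
    len <- 0L
    end_found <- FALSE
    repeat {
      if (!circular && q + 3L > L) break
      len <- len + 3L
      if (len > L) break
      if (codon_at(q) %in% stops) {
        end_found <- TRUE
        break
      }
      q <- q + 3L
    }
    if (!end_found || len < min_len) next
    # backward: a stop must come before any other start; look-back bounded
    # by (roughly) one full turn on circular genomes
    back <- 3L
    valid <- NA
    while (if (circular) back <= L - 3L else p - back >= 0L) {
      pos <- if (circular) ((p - back) %% L + L) %% L else p - back
      cod <- codon_at(pos)
      if (cod %in% stops) {
        valid <- TRUE
        break
      }
      if (cod %in% starts) {
        valid <- FALSE
        break
      }
      back <- back + 3L
    }
    if (is.na(valid)) valid <- !circular  # linear: string start bounds segment
    if (valid) res[[length(res) + 1L]] <- c(start = p, len = len)
  }
  res
}

# Full oracle over both strands; returns sorted "start end strand" keys in
# the package's forward-strand half-open convention.
oracle_orfs <- function(seq, table_id, min_len = 150L, circular = FALSE,
                        starts = c("ATG", "GTG", "TTG")) {
  tt <- translation_table(table_id)
  L <- nchar(seq)
  keys <- character(0)
  for (hit in oracle_strand(seq, tt$stops, starts, min_len, circular)) {
    keys <- c(keys, paste(hit[["start"]], hit[["start"]] + hit[["len"]], "+"))
  }
  rc <- reverse_complement(seq)
  for (hit in oracle_strand(rc, tt$stops, starts, min_len, circular)) {
    fstart <- L - hit[["start"]] - hit[["len"]]
    if (circular) fstart <- ((fstart %% L) + L) %% L
    keys <- c(keys, paste(fstart, fstart + hit[["len"]], "-"))
  }
  sort(keys)
}

orf_keys <- function(orfs) sort(paste(orfs$start, orfs$end, orfs$strand))

# Window-by-window Hamming distances, written naively (the gap-free
# alignment oracle for spacer matching).
hamming_scan_oracle <- function(seq, pattern) {
  r <- nchar(pattern)
  M <- nchar(seq)
  p <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  vapply(seq_len(M - r + 1L), function(i) {
    sum(strsplit(substr(seq, i, i + r - 1L), "", fixed = TRUE)[[1L]] != p)
  }, numeric(1))
}
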