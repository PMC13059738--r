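#' Genome record
#'
#' A named nucleotide sequence with a declared topology. Sequences are stored
#' linearised over the alphabet `{A,C,G,T,N}`; all window and ORF logic
#' consults the topology flag. Circular replicons (e.g. phage genomes
#' assembled as circular DNA molecules) carry `topology = "circular"`.
#'
#' @param id sequence identifier (non-empty, unique within a set).
#' @param seq nucleotide string; lowercase is normalised to uppercase and
#'   IUPAC ambiguity codes map to `N`. Characters outside the IUPAC alphabet
#'   also map to `N`, with a warning giving the count.
#' @param topology `"linear"` or `"circular"`.
#' @param description free-text description.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(id, seq, topology = c("linear", "circular"),
                          description = "") {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty sequence for record '", id, "'")
  iupac <- "ACGTNRYSWKMBDHV"
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% strsplit(iupac, "")[[1L]])
  if (any(bad)) {
    warning(sum(bad), " non-IUPAC character(s) in '", id, "' mapped to N")
  }
  amb <- chars %in% strsplit("RYSWKMBDHV", "")[[1L]] | bad
  if (any(amb)) {
    chars[amb] <- "N"
    seq <- paste(chars, collapse = "")
  }
  structure(
    list(id = id, seq = seq, topology = topology, description = description),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf(
    "<genome_record '%s'> %d nt, %s%s\n",
    x$id, nchar(x$seq), x$topology,
    if (nzchar(x$description)) paste0(" | ", x$description) else ""
  ))
  invisible(x)
}

genome_length <- function(genome) nchar(genome$seq)

#' Read genome records from FASTA
#'
#' Sequences are normalised on read (uppercase; IUPAC ambiguity codes and
#' anything outside the IUPAC alphabet become `N`). A description token
#' `circular=true` marks a record as circular; otherwise the `topology`
#' argument applies to all records.
#'
#' @param path FASTA file.
#' @param topology default topology for records without a `circular=true`
#'   description token.
#' @return list of [genome_record()] objects.
#' @export
read_fasta <- function(path, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  lapply(seq_along(set), function(i) {
    topo <- if (grepl("circular=true", descs[i], fixed = TRUE)) "circular" else topology
    genome_record(ids[i], as.character(set[[i]]), topo, descs[i])
  })
}

#' Write genome records to FASTA
#'
#' 60-column wrapping; circular records gain a `circular=true` description
#' token so that topology round-trips.
#'
#' @param records list of [genome_record()] objects (a single record is
#'   accepted).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "genome_record")) records <- list(records)
  headers <- vapply(records, function(r) {
    desc <- r$description
    if (r$topology == "circular" && !grepl("circular=true", desc, fixed = TRUE)) {
      desc <- trimws(paste(desc, "circular=true"))
    }
    if (nzchar(desc)) paste(r$id, desc) else r$id
  }, character(1))
  set <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "seq"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' GC content of a sequence
#'
#' `(G + C) / (A + C + G + T)`; `N` is excluded from the denominator.
#' An all-`N` sequence has undefined GC content, reported as `NA`.
#'
#' @param seq nucleotide string (or a [genome_record()]).
#' @return real in `[0, 1]`, or `NA` if no unambiguous base is present.
#' @examples
#' gc_content("ACGTN") # 0.5
#' @export
gc_content <- function(seq) {
  if (inherits(seq, "genome_record")) seq <- seq$seq
  stopifnot(nzchar(seq))
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  gc <- sum(chars %in% c("G", "C"))
  acgt <- sum(chars %in% c("A", "C", "G", "T"))
  if (acgt == 0L) return(NA_real_)
  gc / acgt
}

#' Sliding-window GC skew
#'
#' Per-window `(G - C) / (G + C)`, with a cumulative track (the running sum
#' of per-window skews). Windows with `G + C = 0` are recorded as missing
#' (`NA`), never as 0, and contribute nothing to the cumulative sum. On
#' circular genomes windows wrap across the origin; window starts advance by
#' `step` from position 1 while they remain within the (wrapped) sequence.
#'
#' @param genome a [genome_record()] or plain nucleotide string (treated as
#'   linear).
#' @param window window size in nt (`>= 1`).
#' @param step step between window starts in nt; defaults to `window`
#'   (non-overlapping).
#' @return a data.frame of class `skew_track` with columns `start` (0-based),
#'   `end`, `skew`, `cumulative`.
#' @examples
#' gc_skew("GCGGCC", window = 3, step = 3)$skew # 1/3, -1/3
#' @export
gc_skew <- function(genome, window, step = window) {
  if (!inherits(genome, "genome_record")) {
    genome <- genome_record("seq", genome, "linear")
  }
  stopifnot(window >= 1L, step >= 1L)
  L <- genome_length(genome)
  circular <- genome$topology == "circular"
  if (window > L) {
    stop("window (", window, ") exceeds genome length (", L, ")")
  }
  s <- if (circular) paste0(genome$seq, substr(genome$seq, 1L, window)) else genome$seq
  starts <- seq.int(0L, if (circular) L - 1L else L - window, by = step)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  cg <- cumsum(chars == "G")
  cc <- cumsum(chars == "C")
  nG <- cg[starts + window] - c(0L, cg)[starts + 1L]
  nC <- cc[starts + window] - c(0L, cc)[starts + 1L]
  denom <- nG + nC
  skew <- ifelse(denom == 0L, NA_real_, (nG - nC) / denom)
  cum <- cumsum(ifelse(is.na(skew), 0, skew))
  out <- data.frame(start = starts, end = starts + window,
                    skew = skew, cumulative = cum)
  attr(out, "window") <- window
  attr(out, "step") <- step
  class(out) <- c("skew_track", "data.frame")
  out
}

#' Codon usage of a set of ORFs
#'
#' Counts all in-frame codons (coding strand, terminal stop included) across
#' a set of ORFs. The total equals the summed ORF lengths divided by 3.
#'
#' @param orfs an ORF table as returned by [find_orfs()] (needs columns
#'   `seq` and, for error messages, `orf_id`), or a character vector of
#'   in-frame nucleotide sequences.
#' @return named integer vector over all 64 codons (zeros included); codons
#'   containing `N` are tallied under their literal string in addition.
#' @export
codon_usage <- function(orfs) {
  seqs <- if (is.character(orfs)) {
    nm <- names(orfs)
    if (is.null(nm)) nm <- sprintf("orf%d", seq_along(orfs))
    setNames(orfs, nm)
  } else {
    setNames(orfs$seq, orfs$orf_id)
  }
  counts <- setNames(integer(length(ALL_CODONS)), ALL_CODONS)
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[[i]])
    if (n %% 3L != 0L) {
      stop("ORF '", names(seqs)[i], "' has length ", n, ", not divisible by 3")
    }
    if (n == 0L) next
    tab <- table(split_codons(seqs[[i]]))
    for (cd in names(tab)) {
      counts[cd] <- (if (cd %in% names(counts)) counts[[cd]] else 0L) +
        as.integer(tab[[cd]])
    }
  }
  counts
}

#' Write an ORF table as GFF3
#'
#' Feature type `CDS`; coordinates convert from the internal 0-based
#' half-open convention to GFF3's 1-based inclusive convention. Attributes
#' carry the calling translation table and the origin-wrap flag; for ORFs
#' that wrap the origin of a circular genome, `end` exceeds the sequence
#' length (the common convention for circular contigs).
#'
#' @param orfs ORF table from [find_orfs()].
#' @param path output file.
#' @param source source column value.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(orfs, path, source = "phagecode") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(orfs)) {
    lines <- sprintf(
      "%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;table_id=%d;wraps_origin=%s",
      orfs$genome_id, source, orfs$start + 1L, orfs$end, orfs$strand,
      orfs$orf_id, orfs$table_id, tolower(orfs$wraps_origin)
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a codon-usage table as TSV
#'
#' Fixed column order: `codon`, `count`, `frequency`.
#'
#' @param usage named counts from [codon_usage()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_codon_usage <- function(usage, path) {
  total <- sum(usage)
  df <- data.frame(
    codon = names(usage),
    count = as.integer(usage),
    frequency = if (total > 0) as.numeric(usage) / total else 0
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
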