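# Genetic-code assignment by internal-stop disruption.
#
# In genomes using translation table 25 (TGA = glycine), calling ORFs under
# the standard bacterial table 11 truncates every gene whose reading frame
# contains an in-frame TGA: the gene is "disrupted". The fraction of
# table-25 ORFs carrying at least one internal TGA, together with the
# coding-density gain of table 25 over table 11, assigns the code.

#' Count internal stops of an ORF under another table
#'
#' Number of non-terminal codons of an ORF (its terminal stop excluded) that
#' are stop codons under `other_table`. For an ORF called under table 25 and
#' compared against table 11, this counts the in-frame internal TGA codons.
#'
#' @param orf one row of a [find_orfs()] table, or an in-frame nucleotide
#'   string (stop codon included).
#' @param other_table a `translation_table` or NCBI table number.
#' @return integer count.
#' @export
count_internal_stops <- function(orf, other_table) {
  seq <- if (is.character(orf)) orf else orf$seq
  tt <- as_translation_table(other_table)
  codons <- split_codons(toupper(seq))
  if (length(codons) < 2L) return(0L)
  sum(codons[-length(codons)] %in% tt$stops)
}

#' Internal-stop disruption statistic
#'
#' For ORFs called under the candidate alternative code (table 25), computes
#' `n` (ORF count), `k` (ORFs with at least one internal stop of the
#' reference table — i.e. disrupted when translated under it) and
#' `fraction = k / n`.
#'
#' @param orfs ORF table from [find_orfs()] (called under the alternative
#'   table).
#' @param reference_table the table whose stops disrupt; default 11.
#' @return list with `n`, `k`, `fraction` (`NA` when `n = 0`), and
#'   `disrupted` (logical vector over ORFs).
#' @export
disruption_statistic <- function(orfs, reference_table = 11) {
  tt <- as_translation_table(reference_table)
  disrupted <- vapply(
    orfs$seq, function(s) count_internal_stops(s, tt) > 0L, logical(1),
    USE.NAMES = FALSE
  )
  n <- nrow(orfs)
  k <- sum(disrupted)
  list(n = n, k = k, fraction = if (n > 0L) k / n else NA_real_,
       disrupted = disrupted)
}

coding_density <- function(orfs, L) {
  if (!nrow(orfs)) return(0)
  st <- orfs$start
  en <- orfs$end
  # split origin-wrapping intervals into their two arcs
  wrap <- en > L
  ir <- IRanges::IRanges(
    start = c(st + 1L, rep(1L, sum(wrap))),
    end = c(pmin(en, L), en[wrap] - L)
  )
  sum(IRanges::width(IRanges::reduce(ir))) / L
}

#' Assess candidate genetic codes for a genome
#'
#' Calls ORFs under each candidate table, computes per-table ORF counts and
#' coding densities plus the internal-TGA disruption statistic of the
#' alternative code's ORFs against the standard code, and assigns a code:
#' the alternative table (25) is assigned when the disruption fraction is at
#' least `threshold_fraction` AND the coding-density gain of table 25 over
#' table 11 is at least `density_margin`; otherwise the standard table (11)
#' is assigned. With no TGA anywhere both ORF sets coincide and the lower
#' table id wins the tie.
#'
#' @param genome a [genome_record()].
#' @param candidate_tables two distinct NCBI table numbers; default
#'   `c(11, 25)`. The lower id is the reference code, the higher the
#'   alternative.
#' @param min_len,start_codons passed to [find_orfs()].
#' @param threshold_fraction minimum disruption fraction supporting the
#'   alternative code (default 0.10).
#' @param density_margin minimum coding-density gain of the alternative code
#'   (default 0.05).
#' @return list of class `code_assessment`: `genome_id`, `tables` (per-table
#'   data.frame with `table_id`, `orf_count`, `total_coding_nt`,
#'   `coding_density`), `disruption` (`n`, `k`, `fraction`),
#'   `assigned_table`, `rationale`.
#' @export
assess_codes <- function(genome, candidate_tables = c(11, 25),
                         min_len = 150L, start_codons = NULL,
                         threshold_fraction = 0.10, density_margin = 0.05) {
  stopifnot(length(candidate_tables) == 2L,
            candidate_tables[1] != candidate_tables[2])
  tabs <- sort(as.integer(candidate_tables))
  L <- genome_length(genome)
  if (L < min_len) stop("genome '", genome$id, "' shorter than min_len")
  calls <- lapply(tabs, function(tid) {
    find_orfs(genome, tid, min_len = min_len, start_codons = start_codons)
  })
  names(calls) <- as.character(tabs)
  per_table <- do.call(rbind, lapply(seq_along(tabs), function(i) {
    o <- calls[[i]]
    data.frame(
      table_id = tabs[i], orf_count = nrow(o),
      total_coding_nt = sum(o$length),
      coding_density = coding_density(o, L)
    )
  }))
  ds <- disruption_statistic(calls[[2L]], reference_table = tabs[1L])
  gain <- per_table$coding_density[2L] - per_table$coding_density[1L]
  alt <- !is.na(ds$fraction) && ds$fraction >= threshold_fraction &&
    gain >= density_margin
  assigned <- if (alt) tabs[2L] else tabs[1L]
  structure(list(
    genome_id = genome$id,
    tables = per_table,
    disruption = ds[c("n", "k", "fraction")],
    assigned_table = assigned,
    rationale = sprintf(
      "disruption %d/%d = %s (threshold %.2f); density gain %.4f (margin %.2f) -> table %d",
      ds$k, ds$n, ifelse(is.na(ds$fraction), "NA", sprintf("%.4f", ds$fraction)),
      threshold_fraction, gain, density_margin, assigned
    )
  ), class = "code_assessment")
}

#' @export
print.code_assessment <- function(x, ...) {
  cat(sprintf("<code_assessment '%s'> assigned table %d\n  %s\n",
              x$genome_id, x$assigned_table, x$rationale))
  invisible(x)
}

#' Write code assessments as a TSV summary
#'
#' One row per genome: `genome`, `n`, `k`, `fraction`, `density_11`,
#' `density_25` (columns named after the candidate tables), `assigned_table`.
#'
#' @param assessments list of `code_assessment` objects (or one).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_code_summary <- function(assessments, path) {
  if (inherits(assessments, "code_assessment")) assessments <- list(assessments)
  rows <- lapply(assessments, function(a) {
    r <- data.frame(
      genome = a$genome_id, n = a$disruption$n, k = a$disruption$k,
      fraction = a$disruption$fraction
    )
    for (i in seq_len(nrow(a$tables))) {
      r[[paste0("density_", a$tables$table_id[i])]] <- a$tables$coding_density[i]
    }
    r$assigned_table <- a$assigned_table
    r
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
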