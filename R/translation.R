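#' Reverse complement of a DNA string
#'
#' @param seq character scalar over the DNA alphabet (IUPAC letters allowed;
#'   `N` maps to `N`).
#' @return character scalar, the reverse complement.
#' @examples
#' reverse_complement("TCA") # "TGA"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

ALL_CODONS <- as.vector(outer(
  as.vector(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"), paste0)),
  c("T", "C", "A", "G"),
  paste0
))

#' NCBI translation table
#'
#' Builds a translation-table object from the NCBI genetic-code registry
#' (via [Biostrings::getGeneticCode()]). Table 11 is the standard
#' bacterial/archaeal code (stops TAA, TAG, TGA); table 25 is the
#' Candidate Division SR1 / Gracilibacteria code, in which TGA encodes
#' glycine and only TAA and TAG terminate translation. The two tables
#' differ at TGA only.
#'
#' @param table_id NCBI translation table number (integer or string).
#' @param start_codons codons treated as translation starts by the ORF
#'   finder; default `c("ATG", "GTG", "TTG")`, the common prokaryotic set.
#' @return an object of class `translation_table` with fields `table_id`,
#'   `codon_map` (named character vector over the 64 codons, `"*"` for
#'   stop), `stops` and `starts`.
#' @examples
#' tt25 <- translation_table(25)
#' tt25$codon_map[["TGA"]] # "G"
#' @export
translation_table <- function(table_id, start_codons = c("ATG", "GTG", "TTG")) {
  id <- as.character(as.integer(table_id))
  map <- Biostrings::getGeneticCode(id)
  map <- setNames(as.character(map), names(map))
  structure(
    list(
      table_id = as.integer(table_id),
      codon_map = map,
      stops = names(map)[map == "*"],
      starts = start_codons
    ),
    class = "translation_table"
  )
}

#' @export
print.translation_table <- function(x, ...) {
  cat(sprintf(
    "<translation_table %d> stops: %s; starts: %s\n",
    x$table_id, paste(x$stops, collapse = ","), paste(x$starts, collapse = ",")
  ))
  invisible(x)
}

as_translation_table <- function(table) {
  if (inherits(table, "translation_table")) table else translation_table(table)
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    stop("sequence length ", n, " is not divisible by 3")
  }
  if (n == 0L) return(character(0))
  at <- seq.int(1L, n, by = 3L)
  substring(seq, at, at + 2L)
}

#' Translate a nucleotide sequence
#'
#' Codon-wise translation under a given table. Stop codons render as `"*"`.
#' Any codon containing a character outside `A`, `C`, `G`, `T` (including
#' `N`) translates to `"X"`: ambiguity never creates or destroys a stop.
#'
#' @param seq nucleotide string whose length is divisible by 3.
#' @param table a `translation_table` or an NCBI table number.
#' @return amino-acid string.
#' @examples
#' translate_seq("TGA", 25) # "G"
#' translate_seq("TGA", 11) # "*"
#' translate_seq("ATGNNN", 11) # "MX"
#' @export
translate_seq <- function(seq, table) {
  tt <- as_translation_table(table)
  codons <- split_codons(toupper(seq))
  aa <- tt$codon_map[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
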