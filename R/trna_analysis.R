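# Suppressor-tRNA classification and codon-usage compatibility.
#
# tRNA genes are consumed from tabular annotations (tRNAscan-SE-like:
# name, begin, end, isotype, anticodon); de novo tRNA discovery by
# covariance models is an external problem. A tRNA whose anticodon decodes
# a stop codon of the genome's nominal table is a suppressor: the anticodon
# TCA reads UGA, reassigning it (to glycine in table 25).

#' Decode an anticodon to the codon it reads
#'
#' The decoded codon is the reverse complement of the anticodon (both given
#' 5'->3').
#'
#' @param anticodon 3-nt DNA string over `{A,C,G,T}`.
#' @return 3-nt codon string.
#' @examples
#' decode_anticodon("TCA") # "TGA"
#' @export
decode_anticodon <- function(anticodon) {
  anticodon <- toupper(anticodon)
  if (nchar(anticodon) != 3L || grepl("[^ACGT]", anticodon)) {
    stop("invalid anticodon '", anticodon, "': must be 3 nt over ACGT")
  }
  reverse_complement(anticodon)
}

#' Is a tRNA a suppressor under a given table?
#'
#' `TRUE` iff the decoded codon is a stop codon of `table`. A tRNA reading
#' TGA is a suppressor under table 11 but not under table 25, where TGA is
#' an ordinary glycine codon.
#'
#' @param trna a 3-nt anticodon string, or a list/row with an `anticodon`
#'   field.
#' @param table a `translation_table` or NCBI table number.
#' @return logical.
#' @export
classify_suppressor <- function(trna, table) {
  anticodon <- if (is.character(trna) && length(trna) == 1L) trna else trna$anticodon
  tt <- as_translation_table(table)
  decode_anticodon(anticodon) %in% tt$stops
}

# Isotype of a decoded codon: three-letter amino acid under table 11; for
# stop-decoding (suppressor) anticodons, the table-25 meaning where one
# exists (TGA -> Gly), otherwise the generic label "Sup".
AA1TO3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val"
)

isotype_of <- function(codon) {
  aa11 <- translation_table(11)$codon_map[[codon]]
  if (aa11 != "*") return(AA1TO3[[aa11]])
  aa25 <- translation_table(25)$codon_map[[codon]]
  if (aa25 != "*") AA1TO3[[aa25]] else "Sup"
}

#' Read / write a tRNA annotation table
#'
#' TSV with columns `name`, `begin`, `end`, `isotype`, `anticodon`
#' (tRNAscan-SE-like). Coordinates are 1-based inclusive as annotation
#' tools emit them.
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
read_trna_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "begin", "end", "isotype", "anticodon")
  if (!all(need %in% names(df))) {
    stop("tRNA table ", path, " must have columns: ", paste(need, collapse = ", "))
  }
  df[need]
}

#' @rdname read_trna_table
#' @param trnas tRNA data.frame.
#' @export
write_trna_table <- function(trnas, path) {
  write.table(trnas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify a tRNA table against a translation table
#'
#' Adds the decoded codon, the suppressor flag, the isotype implied by the
#' decoded codon, and whether the input's isotype label disagrees with it
#' (disagreements are reported, never corrected).
#'
#' @param trnas data.frame as from [read_trna_table()].
#' @param table nominal table for suppressor calling (default 11: a
#'   suppressor reads a standard-code stop).
#' @return the input with columns `codon`, `suppressor`, `isotype_decoded`,
#'   `isotype_mismatch` appended.
#' @export
classify_trnas <- function(trnas, table = 11) {
  tt <- as_translation_table(table)
  codons <- vapply(trnas$anticodon, decode_anticodon, character(1),
                   USE.NAMES = FALSE)
  trnas$codon <- codons
  trnas$suppressor <- codons %in% tt$stops
  trnas$isotype_decoded <- vapply(codons, isotype_of, character(1),
                                  USE.NAMES = FALSE)
  trnas$isotype_mismatch <- trnas$isotype != trnas$isotype_decoded
  trnas
}

#' Phage/host codon-usage compatibility of tRNA-decoded codons
#'
#' For each tRNA's decoded codon, counts its in-frame occurrences in the
#' phage and host coding sequences and reports whether the codon is used by
#' both (both counts positive). Matches the check that all codons read by
#' phage-encoded tRNAs are in use in both the phage and its host.
#'
#' @param trnas tRNA data.frame (needs `anticodon`; other columns kept).
#' @param phage_orfs,host_orfs ORF tables from [find_orfs()] (or character
#'   vectors of in-frame sequences). Empty sets give zero counts.
#' @return data.frame: `name`, `anticodon`, `codon`, `phage_count`,
#'   `host_count`, `used_by_both`.
#' @export
codon_compatibility <- function(trnas, phage_orfs, host_orfs) {
  if (nrow(trnas) == 0L) {
    return(data.frame(name = character(0), anticodon = character(0),
                      codon = character(0), phage_count = integer(0),
                      host_count = integer(0), used_by_both = logical(0)))
  }
  usage_of <- function(orfs) {
    n <- if (is.character(orfs)) length(orfs) else nrow(orfs)
    if (n == 0L) setNames(integer(length(ALL_CODONS)), ALL_CODONS)
    else codon_usage(orfs)
  }
  pu <- usage_of(phage_orfs)
  hu <- usage_of(host_orfs)
  codons <- vapply(trnas$anticodon, decode_anticodon, character(1),
                   USE.NAMES = FALSE)
  pc <- as.integer(pu[codons])
  hc <- as.integer(hu[codons])
  pc[is.na(pc)] <- 0L
  hc[is.na(hc)] <- 0L
  data.frame(
    name = if ("name" %in% names(trnas)) trnas$name else codons,
    anticodon = trnas$anticodon, codon = codons,
    phage_count = pc, host_count = hc,
    used_by_both = pc > 0L & hc > 0L
  )
}
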