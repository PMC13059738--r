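# Single-copy marker completeness / redundancy of a genome bin.
#
# Copy counts come from upstream homology searches; this module does the
# arithmetic. The canonical set size here is 43, the size of the bacterial
# single-copy gene list adapted to patescibacterial (CPR) genomes: with 41
# of 43 markers present, completeness is 95.35%.

#' Load a marker-set definition
#'
#' A marker set is a plain list of marker names, one per line (comment lines
#' starting with `#` and a `marker` header line are skipped). The package
#' ships a placeholder 43-name set of standard bacterial single-copy genes
#' at `system.file("extdata", "marker_set_43_placeholder.tsv",
#' package = "phagecode")`; any user-supplied list is accepted.
#'
#' @param path file of marker names; default the shipped placeholder set.
#' @return character vector of marker names.
#' @export
read_marker_set <- function(path = system.file("extdata",
                                               "marker_set_43_placeholder.tsv",
                                               package = "phagecode")) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & lines != "marker"]
  unique(lines)
}

#' Construct a marker table
#'
#' @param copy_counts named non-negative integer vector: marker name ->
#'   copy count. Markers of the set absent from `copy_counts` count as 0.
#' @param marker_set character vector of marker names defining the set;
#'   every name in `copy_counts` must belong to it.
#' @param name marker-set label.
#' @return object of class `marker_table` with fields `marker_set_name`,
#'   `entries` (full named vector over the set), `set_size`.
#' @export
marker_table <- function(copy_counts, marker_set, name = "marker_set") {
  stopifnot(length(marker_set) >= 1L)
  if (is.null(names(copy_counts)) && length(copy_counts) > 0L) {
    stop("copy_counts must be named by marker")
  }
  unknown <- setdiff(names(copy_counts), marker_set)
  if (length(unknown)) {
    stop("markers not in the declared set: ", paste(unknown, collapse = ", "))
  }
  if (any(copy_counts < 0)) stop("copy counts must be non-negative")
  entries <- setNames(integer(length(marker_set)), marker_set)
  entries[names(copy_counts)] <- as.integer(copy_counts)
  structure(
    list(marker_set_name = name, entries = entries,
         set_size = length(marker_set)),
    class = "marker_table"
  )
}

#' Read a marker copy-count table from TSV
#'
#' Columns `marker`, `copy_count`.
#'
#' @param path TSV path.
#' @param marker_set marker-name vector (default the shipped set).
#' @param name marker-set label.
#' @return a [marker_table()].
#' @export
read_marker_counts <- function(path, marker_set = read_marker_set(),
                               name = "marker_set") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("marker", "copy_count") %in% names(df))) {
    stop("marker table ", path, " must have columns marker, copy_count")
  }
  marker_table(setNames(df$copy_count, df$marker), marker_set, name)
}

#' Completeness of a genome bin
#'
#' `100 * (markers with copy count >= 1) / set size`, rounded to 2 decimals.
#'
#' @param table a [marker_table()].
#' @return percentage in `[0, 100]`.
#' @examples
#' ms <- paste0("m", 1:43)
#' tb <- marker_table(setNames(rep(1L, 41), ms[1:41]), ms)
#' completeness(tb) # 95.35
#' @export
completeness <- function(table) {
  stopifnot(inherits(table, "marker_table"), table$set_size >= 1L)
  round(100 * sum(table$entries >= 1L) / table$set_size, 2)
}

#' Redundancy of a genome bin
#'
#' `100 * (markers with copy count >= 2) / set size`, rounded to 2 decimals.
#'
#' @param table a [marker_table()].
#' @return percentage in `[0, 100]`.
#' @examples
#' ms <- paste0("m", 1:43)
#' tb <- marker_table(setNames(c(rep(2L, 4), rep(1L, 39)), ms), ms)
#' redundancy(tb) # 9.3
#' @export
redundancy <- function(table) {
  stopifnot(inherits(table, "marker_table"), table$set_size >= 1L)
  round(100 * sum(table$entries >= 2L) / table$set_size, 2)
}

#' Marker QC summary
#'
#' @param table a [marker_table()].
#' @return list `{completeness, redundancy, present, multicopy, set_size}`
#'   (the JSON report layout).
#' @export
marker_qc_summary <- function(table) {
  list(
    completeness = completeness(table),
    redundancy = redundancy(table),
    present = sum(table$entries >= 1L),
    multicopy = sum(table$entries >= 2L),
    set_size = table$set_size
  )
}

#' @export
print.marker_table <- function(x, ...) {
  s <- marker_qc_summary(x)
  cat(sprintf(
    "<marker_table '%s'> %d markers: %d present, %d multi-copy; completeness %.2f%%, redundancy %.2f%%\n",
    x$marker_set_name, s$set_size, s$present, s$multicopy,
    s$completeness, s$redundancy
  ))
  invisible(x)
}
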