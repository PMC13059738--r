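# Pipeline orchestration: compose the analysis stages on a set of inputs
# and emit one combined JSON report per run. Stages run independently per
# genome; a stage with no inputs is marked "skipped" in the report.

default_config <- function() {
  list(
    genomes = NULL,            # FASTA path or list of genome_record
    topology = "linear",
    candidate_tables = c(11L, 25L),
    min_orf_len = 150L,
    start_codons = c("ATG", "GTG", "TTG"),
    threshold_fraction = 0.10,
    density_margin = 0.05,
    trna_table = NULL,         # TSV path or data.frame
    host_genome = NULL,        # FASTA path or genome_record (codon usage)
    crispr_repeat = NULL,      # repeat sequence (string)
    crispr_source = NULL,      # array-bearing FASTA path or genome_record
    crispr_targets = NULL,     # FASTA path or list of genome_record
    repeat_tolerance = 0L,
    min_identity = 95,
    min_coverage = 95,
    marker_counts = NULL,      # TSV path or named copy-count vector
    marker_set = NULL,         # marker-name file; default shipped set
    skew_window = NULL,        # default genome/100
    skew_step = NULL,          # default window/2
    seed = 1L,
    out_dir = NULL
  )
}

#' Build a pipeline run configuration
#'
#' Starts from package defaults and applies a YAML config file and then any
#' direct overrides (flags beat config, config beats defaults).
#'
#' @param config_file optional YAML file of settings.
#' @param ... direct overrides (see Details for keys).
#' @details Keys: `genomes`, `topology`, `candidate_tables`, `min_orf_len`,
#'   `start_codons`, `threshold_fraction`, `density_margin`, `trna_table`,
#'   `host_genome`, `crispr_repeat`, `crispr_source`, `crispr_targets`,
#'   `repeat_tolerance`, `min_identity`, `min_coverage`, `marker_counts`,
#'   `marker_set`, `skew_window`, `skew_step`, `seed`, `out_dir`.
#' @return named list of class `run_config`.
#' @export
run_config <- function(config_file = NULL, ...) {
  cfg <- default_config()
  if (!is.null(config_file)) {
    cfg <- modifyList(cfg, yaml::read_yaml(config_file))
  }
  overrides <- list(...)
  cfg <- modifyList(cfg, overrides)
  stopifnot(cfg$min_identity >= 0, cfg$min_identity <= 100,
            cfg$min_coverage >= 0, cfg$min_coverage <= 100)
  class(cfg) <- c("run_config", "list")
  cfg
}

as_records <- function(x, topology = "linear") {
  if (is.null(x)) return(NULL)
  if (inherits(x, "genome_record")) return(list(x))
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(read_fasta(x, topology = topology))
  }
  if (is.list(x)) return(x)
  stop("cannot interpret genome input")
}

#' Run the analysis pipeline
#'
#' Executes, for each input genome: ORF calling under the candidate tables
#' and genetic-code assessment; GC-skew track; then (when inputs are
#' present) tRNA classification and codon-usage compatibility, CRISPR array
#' extraction and spacer matching, and marker QC. Writes a combined JSON
#' report (plus per-stage TSV/GFF3 files) when `out_dir` is set. Outputs
#' are deterministic given the configuration and seed; the seed is recorded
#' in the report.
#'
#' @param config a [run_config()].
#' @return the report, a list of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  genomes <- as_records(config$genomes, config$topology)
  if (is.null(genomes) || !length(genomes)) stop("no input genomes")
  with_seed(config$seed, {
    report <- list(
      tool = "phagecode",
      seed = config$seed,
      parameters = list(
        candidate_tables = as.integer(config$candidate_tables),
        min_orf_len = as.integer(config$min_orf_len),
        threshold_fraction = config$threshold_fraction,
        density_margin = config$density_margin,
        min_identity = config$min_identity,
        min_coverage = config$min_coverage,
        repeat_tolerance = as.integer(config$repeat_tolerance)
      ),
      genomes = list(),
      crispr = list(status = "skipped"),
      markers = list(status = "skipped")
    )

    host_usage_orfs <- NULL
    if (!is.null(config$host_genome)) {
      host <- as_records(config$host_genome, config$topology)[[1L]]
      host_usage_orfs <- find_orfs(host, max(config$candidate_tables),
                                   min_len = config$min_orf_len,
                                   start_codons = config$start_codons)
    }

    for (g in genomes) {
      entry <- list(id = g$id, length = genome_length(g),
                    topology = g$topology,
                    gc_content = gc_content(g))
      assess <- assess_codes(
        g, candidate_tables = config$candidate_tables,
        min_len = config$min_orf_len, start_codons = config$start_codons,
        threshold_fraction = config$threshold_fraction,
        density_margin = config$density_margin
      )
      entry$code_assessment <- list(
        tables = assess$tables,
        disruption = assess$disruption,
        assigned_table = assess$assigned_table,
        rationale = assess$rationale
      )
      win <- config$skew_window
      if (is.null(win)) win <- max(1L, genome_length(g) %/% 100L)
      stp <- config$skew_step
      if (is.null(stp)) stp <- max(1L, win %/% 2L)
      skew <- gc_skew(g, window = win, step = stp)
      entry$gc_skew <- list(window = win, step = stp,
                            n_windows = nrow(skew),
                            cumulative_final = skew$cumulative[nrow(skew)])
      tr <- detect_terminal_repeats(g$seq)
      entry$terminal_repeat <- if (is.null(tr)) list(kind = "none") else
        tr[c("kind", "length")]

      if (!is.null(config$trna_table)) {
        trnas <- if (is.data.frame(config$trna_table)) config$trna_table else
          read_trna_table(config$trna_table)
        cls <- classify_trnas(trnas, table = min(config$candidate_tables))
        orfs_alt <- find_orfs(g, max(config$candidate_tables),
                              min_len = config$min_orf_len,
                              start_codons = config$start_codons)
        compat <- codon_compatibility(
          cls, orfs_alt,
          if (is.null(host_usage_orfs)) character(0) else host_usage_orfs
        )
        entry$trna <- list(
          n = nrow(cls), n_suppressors = sum(cls$suppressor),
          records = cls,
          compatibility = if (is.null(host_usage_orfs)) NULL else compat
        )
      } else {
        entry$trna <- list(status = "skipped")
      }
      report$genomes[[g$id]] <- entry
    }

    if (!is.null(config$crispr_repeat) && !is.null(config$crispr_source)) {
      src <- as_records(config$crispr_source, config$topology)[[1L]]
      arr <- extract_spacers(src, config$crispr_repeat,
                             max_mismatches = config$repeat_tolerance)
      crispr <- list(
        status = "run",
        source = src$id,
        n_repeats = nrow(arr$repeat_occurrences),
        n_spacers = nrow(arr$spacers)
      )
      if (nrow(arr$spacers) && !is.null(config$crispr_targets)) {
        targets <- as_records(config$crispr_targets, config$topology)
        mask <- NULL
        src_in_targets <- vapply(targets, function(t) t$id == src$id,
                                 logical(1))
        if (any(src_in_targets) && nrow(arr$repeat_occurrences)) {
          mask <- data.frame(
            target_id = src$id,
            start = min(arr$repeat_occurrences$start),
            end = max(arr$repeat_occurrences$end)
          )
        }
        crispr$matches <- match_spacers(
          arr$spacers, targets,
          min_identity = config$min_identity,
          min_coverage = config$min_coverage, mask = mask
        )
        crispr$n_retained <- sum(crispr$matches$retained)
      }
      report$crispr <- crispr
    }

    if (!is.null(config$marker_counts)) {
      set <- if (is.null(config$marker_set)) read_marker_set() else
        read_marker_set(config$marker_set)
      tab <- if (is.character(config$marker_counts) &&
                 length(config$marker_counts) == 1L &&
                 file.exists(config$marker_counts)) {
        read_marker_counts(config$marker_counts, marker_set = set)
      } else {
        marker_table(config$marker_counts, set)
      }
      report$markers <- c(list(status = "run"), marker_qc_summary(tab))
    }

    class(report) <- c("pipeline_report", "list")
    if (!is.null(config$out_dir)) {
      write_report(report, config$out_dir)
    }
    report
  })
}

#' Write a pipeline report as JSON
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @return the JSON path, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Structural check of a pipeline report
#'
#' Verifies the report against the shipped layout description
#' (`inst/schema/report_schema.json`): required top-level keys, per-genome
#' keys, and value types.
#'
#' @param report a `pipeline_report` (or a list parsed from report JSON).
#' @return `TRUE` (invisibly) or an error describing the first violation.
#' @export
validate_report <- function(report) {
  need <- c("tool", "seed", "parameters", "genomes", "crispr", "markers")
  miss <- setdiff(need, names(report))
  if (length(miss)) stop("report missing keys: ", paste(miss, collapse = ", "))
  for (g in report$genomes) {
    gneed <- c("id", "length", "topology", "gc_content", "code_assessment")
    gmiss <- setdiff(gneed, names(g))
    if (length(gmiss)) {
      stop("genome entry missing keys: ", paste(gmiss, collapse = ", "))
    }
    ca <- g$code_assessment
    if (!all(c("disruption", "assigned_table") %in% names(ca))) {
      stop("code_assessment incomplete for genome ", g$id)
    }
  }
  invisible(TRUE)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> seed %d, %d genome(s)\n", x$seed,
              length(x$genomes)))
  for (g in x$genomes) {
    cat(sprintf(
      "  %s: %d nt, assigned table %d (disruption %d/%d)\n",
      g$id, g$length, g$code_assessment$assigned_table,
      g$code_assessment$disruption$k, g$code_assessment$disruption$n
    ))
  }
  if (!identical(x$crispr$status, "skipped")) {
    cat(sprintf("  crispr: %d repeat(s), %d spacer(s)\n",
                x$crispr$n_repeats, x$crispr$n_spacers))
  }
  if (!identical(x$markers$status, "skipped")) {
    cat(sprintf("  markers: completeness %.2f%%, redundancy %.2f%%\n",
                x$markers$completeness, x$markers$redundancy))
  }
  invisible(x)
}
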