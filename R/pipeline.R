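#' Build a pipeline configuration
#'
#' Flat key-value configuration for [run_all()], with every tunable of the
#' stage functions surfaced. Unknown keys are rejected, and thresholds are
#' checked against their documented domains. The config is echoed into the
#' run report for provenance.
#'
#' @param ciri2,circexplorer2,find_circ Caller output paths (any may be
#'   `NULL`; at least one caller file is required).
#' @param genome_fasta,annotation_gtf,proteome_fasta,psm_table,prm_table
#'   Input paths; `annotation_gtf` may be `NULL` (genomic-span fallback for
#'   every circle), `psm_table`/`prm_table` may be `NULL` to skip those
#'   stages.
#' @param out_dir Directory for intermediate and final outputs.
#' @param min_callers,slack Consensus parameters ([build_consensus()]).
#' @param min_aa,start_codons ORF parameters ([find_circular_orfs()]).
#' @param max_missed Digestion parameter ([digest_peptides()]).
#' @param il_equivalence,min_pep_len,max_pep_len Uniqueness-filter
#'   parameters ([filter_unique_peptides()]).
#' @param q_threshold PSM q-value threshold ([map_psms_to_circrnas()]).
#' @param prm_min_transitions PRM floor ([compute_prm_ratios()]).
#' @param strip_chr_prefix Passed to the caller parsers.
#' @return A named list of class `circpep_config`.
#' @export
circpep_config <- function(ciri2 = NULL, circexplorer2 = NULL,
                           find_circ = NULL, genome_fasta = NULL,
                           annotation_gtf = NULL, proteome_fasta = NULL,
                           psm_table = NULL, prm_table = NULL,
                           out_dir = "circpep_out",
                           min_callers = 2L, slack = 0L, min_aa = 20L,
                           start_codons = "ATG", max_missed = 2L,
                           il_equivalence = TRUE, min_pep_len = 7L,
                           max_pep_len = 52L, q_threshold = 0.01,
                           prm_min_transitions = 3L,
                           strip_chr_prefix = FALSE) {
  config <- as.list(environment())
  validate_config(config)
}

config_keys <- c("ciri2", "circexplorer2", "find_circ", "genome_fasta",
                 "annotation_gtf", "proteome_fasta", "psm_table", "prm_table",
                 "out_dir", "min_callers", "slack", "min_aa", "start_codons",
                 "max_missed", "il_equivalence", "min_pep_len", "max_pep_len",
                 "q_threshold", "prm_min_transitions", "strip_chr_prefix")

validate_config <- function(config) {
  unknown <- setdiff(names(config), config_keys)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- formals(circpep_config)
  for (k in setdiff(config_keys, names(config))) {
    config[[k]] <- eval(defaults[[k]])
  }
  stopifnot(
    "min_callers must be >= 1" = config$min_callers >= 1,
    "slack must be >= 0" = config$slack >= 0,
    "min_aa must be >= 1" = config$min_aa >= 1,
    "max_missed must be >= 0" = config$max_missed >= 0,
    "q_threshold must be in [0,1]" = config$q_threshold >= 0 &&
      config$q_threshold <= 1,
    "peptide length bounds must satisfy 1 <= min <= max" =
      config$min_pep_len >= 1 && config$min_pep_len <= config$max_pep_len,
    "prm_min_transitions must be >= 1" = config$prm_min_transitions >= 1
  )
  structure(config, class = "circpep_config")
}

#' Run the full translatable-circRNA pipeline
#'
#' Executes the stages in order — caller parsing, consensus, circle
#' assembly, circular-ORF prediction, digestion + uniqueness filtering,
#' search-database construction, PSM evidence mapping, and (when a PRM
#' table is given) PRM quantification — persisting every intermediate under
#' `out_dir` and logging per-stage record counts. An empty stage result
#' short-circuits the downstream stages cleanly (empty outputs, no error).
#'
#' Missing input files are reported by name before any work is done.
#' Re-running with the same config rewrites identical output content.
#'
#' @param config A [circpep_config()] list, a plain named list of the same
#'   keys, or the path to a YAML file of them.
#' @return An object of class `circpep_run`: the echoed config, a per-stage
#'   count table (see [tidy.circpep_run()]), output paths and the stage
#'   results themselves.
#' @export
run_all <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!inherits(config, "circpep_config")) config <- validate_config(config)

  caller_paths <- Filter(Negate(is.null),
                         config[c("ciri2", "circexplorer2", "find_circ")])
  if (length(caller_paths) == 0) stop("no caller files given", call. = FALSE)
  needed <- c(unlist(caller_paths), config$genome_fasta,
              config$proteome_fasta, config$annotation_gtf,
              config$psm_table, config$prm_table)
  absent <- needed[!file.exists(needed)]
  if (length(absent) > 0) {
    stop("missing input file(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  log_stage <- function(stage, n_in, n_out) {
    message(sprintf("[circpep] %-12s in=%d out=%d", stage, n_in, n_out))
    counts[[length(counts) + 1L]] <<- tibble::tibble(
      stage = stage, n_in = as.integer(n_in), n_out = as.integer(n_out))
  }

  ## consensus
  calls <- dplyr::bind_rows(
    if (!is.null(config$ciri2)) {
      read_ciri2(config$ciri2, strip_chr_prefix = config$strip_chr_prefix)
    },
    if (!is.null(config$circexplorer2)) {
      read_caller_bed(config$circexplorer2, "circexplorer2",
                      strip_chr_prefix = config$strip_chr_prefix)
    },
    if (!is.null(config$find_circ)) {
      read_caller_bed(config$find_circ, "find_circ",
                      strip_chr_prefix = config$strip_chr_prefix)
    }
  )
  consensus <- build_consensus(calls, min_callers = config$min_callers,
                               slack = config$slack)
  write_consensus_bed(consensus, file.path(config$out_dir, "consensus.bed"))
  log_stage("consensus", nrow(calls), nrow(consensus))

  ## circle sequences
  genome <- read_fasta(config$genome_fasta, type = "dna")
  models <- if (is.null(config$annotation_gtf)) NULL else {
    read_gene_models(config$annotation_gtf)
  }
  circ_seqs <- assemble_circ_sequence(consensus, genome, models)
  if (nrow(circ_seqs) > 0) {
    write_circ_fasta(circ_seqs, file.path(config$out_dir, "circles.fa"))
  }
  log_stage("sequence", nrow(consensus), nrow(circ_seqs))

  ## ORFs
  orfs <- find_circular_orfs(circ_seqs, min_aa = config$min_aa,
                             start_codons = config$start_codons)
  if (nrow(orfs) > 0) {
    write_orf_fasta(orfs, file.path(config$out_dir, "orfs.fa"))
  }
  log_stage("orfs", nrow(circ_seqs), nrow(orfs))

  ## peptide database
  proteome <- read_fasta(config$proteome_fasta, type = "protein")
  peptides <- digest_peptides(orfs, max_missed = config$max_missed)
  unique_peps <- filter_unique_peptides(
    peptides, proteome, il_equivalence = config$il_equivalence,
    min_len = config$min_pep_len, max_len = config$max_pep_len
  )
  write_peptide_report(unique_peps, file.path(config$out_dir, "peptides.tsv"))
  write_search_database(orfs, proteome,
                        file.path(config$out_dir, "search_db.fa"))
  log_stage("digest-db", nrow(peptides), nrow(unique_peps))

  ## PSM evidence
  evidence <- NULL
  if (!is.null(config$psm_table)) {
    psms <- read_psm_table(config$psm_table)
    evidence <- map_psms_to_circrnas(psms, unique_peps,
                                     q_threshold = config$q_threshold,
                                     il_equivalence = config$il_equivalence)
    write_evidence_report(evidence, file.path(config$out_dir, "evidence.tsv"))
    log_stage("evidence", nrow(psms), nrow(evidence))
  }

  ## PRM quantification
  prm_ratios <- NULL
  if (!is.null(config$prm_table)) {
    transitions <- read_prm_table(config$prm_table)
    prm_ratios <- compute_prm_ratios(
      transitions, min_transitions = config$prm_min_transitions)
    write_prm_report(prm_ratios, file.path(config$out_dir, "prm_ratios.tsv"))
    log_stage("prm", nrow(transitions), nrow(prm_ratios))
  }

  structure(
    list(
      config = config,
      counts = dplyr::bind_rows(counts),
      consensus = consensus, circ_seqs = circ_seqs, orfs = orfs,
      unique_peptides = unique_peps, evidence = evidence,
      prm_ratios = prm_ratios,
      out_dir = config$out_dir
    ),
    class = "circpep_run"
  )
}

#' @export
print.circpep_run <- function(x, ...) {
  cat("circpep pipeline run\n")
  cat("outputs in:", x$out_dir, "\n\n")
  print(x$counts)
  if (!is.null(x$evidence)) {
    cat("\ntranslatable circRNAs nominated:", nrow(x$evidence),
        "(all flagged for review)\n")
  }
  invisible(x)
}

#' Tidy and summarise a pipeline run
#'
#' `tidy()` returns the per-stage record-count funnel (input and output
#' counts per stage — the numbers a flow-chart figure of the screen would
#' report); `glance()` returns a one-row summary.
#'
#' @param x A [run_all()] result.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy circpep_run
#' @export
tidy.circpep_run <- function(x, ...) {
  x$counts
}

#' @rdname tidy.circpep_run
#' @method glance circpep_run
#' @export
glance.circpep_run <- function(x, ...) {
  tibble::tibble(
    n_consensus_circles = nrow(x$consensus),
    n_orfs = nrow(x$orfs),
    n_unique_peptides = nrow(x$unique_peptides),
    n_translatable = if (is.null(x$evidence)) NA_integer_ else nrow(x$evidence),
    n_prm_precursors = if (is.null(x$prm_ratios)) NA_integer_ else
      nrow(x$prm_ratios)
  )
}
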