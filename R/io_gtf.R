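#' Read gene models (exon chains) from a GTF/GFF file
#'
#' Imports the annotation with rtracklayer, keeps `exon` features, and
#' returns one row per exon in the package-wide 0-based half-open convention.
#' Attribute keys are configurable for annotations that use non-standard
#' names (e.g. `"Parent"` in some GFF3 files).
#'
#' Within each transcript, exons are sorted by genomic coordinate and checked
#' for overlaps and for consistency of chromosome and strand.
#'
#' @param path Path to a GTF or GFF3 file.
#' @param gene_key,tx_key Attribute names holding the gene and transcript
#'   identifiers.
#' @return A tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `exon_start`, `exon_end`, `exon_rank` (1 = most upstream in
#'   transcript orientation).
#' @export
read_gene_models <- function(path, gene_key = "gene_id",
                             tx_key = "transcript_id") {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "exon"]
  meta <- as.data.frame(S4Vectors::mcols(gr))
  if (!all(c(gene_key, tx_key) %in% names(meta))) {
    stop("annotation ", path, " lacks attribute(s): ",
         paste(setdiff(c(gene_key, tx_key), names(meta)), collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    gene_id = as.character(meta[[gene_key]]),
    transcript_id = as.character(meta[[tx_key]]),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    exon_start = GenomicRanges::start(gr) - 1L,  # GTF is 1-based inclusive
    exon_end = GenomicRanges::end(gr)
  )
  validate_gene_models(out, what = path)
}

validate_gene_models <- function(models, what = "gene models") {
  required <- c("gene_id", "transcript_id", "chrom", "strand",
                "exon_start", "exon_end")
  missing <- setdiff(required, names(models))
  if (length(missing) > 0) {
    stop(what, " lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(models$strand %in% c("+", "-"))) {
    stop(what, ": exon strand must be + or -", call. = FALSE)
  }
  out <- models |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::arrange(.data$exon_start, .by_group = TRUE) |>
    dplyr::mutate(
      exon_rank = if (dplyr::first(.data$strand) == "+") {
        dplyr::row_number()
      } else {
        dplyr::n() - dplyr::row_number() + 1L
      }
    ) |>
    dplyr::ungroup()
  per_tx <- out |>
    dplyr::summarise(
      one_chrom = dplyr::n_distinct(.data$chrom) == 1,
      one_strand = dplyr::n_distinct(.data$strand) == 1,
      no_overlap = all(diff_ok(.data$exon_start, .data$exon_end)),
      .by = "transcript_id"
    )
  bad <- per_tx$transcript_id[!(per_tx$one_chrom & per_tx$one_strand &
                                  per_tx$no_overlap)]
  if (length(bad) > 0) {
    stop(what, ": malformed transcript(s) (overlapping exons or mixed ",
         "chrom/strand): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

# exons sorted by start: non-overlap means each start >= previous end
diff_ok <- function(starts, ends) {
  o <- order(starts)
  s <- starts[o]; e <- ends[o]
  if (length(s) <= 1) return(TRUE)
  s[-1] >= e[-length(e)]
}

#' Write gene models as GTF
#'
#' Emits a minimal, well-formed GTF (exon features with `gene_id` and
#' `transcript_id` attributes) from the tibble schema used throughout the
#' package. Coordinates convert back to GTF's 1-based inclusive convention.
#'
#' @param models Gene-model tibble (see [read_gene_models()]).
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return The path, invisibly.
#' @export
write_gtf <- function(models, path, source = "circpep") {
  lines <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    models$chrom, source, models$exon_start + 1L, models$exon_end,
    models$strand, models$gene_id, models$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}
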