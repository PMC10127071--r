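#' Assemble spliced circular sequences for consensus circRNAs
#'
#' For each back-splice junction, finds an annotated transcript whose exon
#' boundaries coincide exactly with both junction ends, concatenates the
#' transcript's exons falling inside `[start, end)` in transcript order, and
#' reverse-complements minus-strand circles. The back-splice joins the last
#' included exon's 3' end back to the first included exon's 5' start, so
#' position 0 of the circle is the acceptor-side base (the start of the most
#' upstream included exon in transcript orientation) — one fixed rotation
#' that makes downstream ORF coordinates reproducible.
#'
#' Transcript choice when several match both boundaries: most exons inside
#' the span, then lexicographically smallest `transcript_id`. When no
#' transcript matches, the unspliced genomic span is used with a warning
#' (`fallback_genomic = FALSE` turns this into an error instead).
#'
#' @param circles A consensus tibble ([build_consensus()]) or any tibble with
#'   `circ_id`, `chrom`, `start`, `end`, `strand` columns.
#' @param genome Named character vector of chromosome sequences
#'   ([read_fasta()]).
#' @param models Gene-model tibble ([read_gene_models()]); may be `NULL` to
#'   force the genomic-span fallback for every circle.
#' @param fallback_genomic Use the unspliced genomic span when no annotated
#'   transcript matches the junction.
#' @return A tibble of class `circ_seq_tbl`: `circ_id`, `chrom`, `start`,
#'   `end`, `strand`, `transcript_id` (`NA` for fallback), `n_exons`,
#'   `sequence` (uppercase, transcript orientation), `length`,
#'   `exon_structure` (list column of genomic exon intervals used).
#' @export
assemble_circ_sequence <- function(circles, genome, models,
                                   fallback_genomic = TRUE) {
  required <- c("circ_id", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(circles))
  if (length(missing) > 0) {
    stop("circles lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(models)) models <- validate_gene_models(models)
  if (nrow(circles) == 0) {
    out <- tibble::tibble(
      circ_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), transcript_id = character(),
      n_exons = integer(), sequence = character(), length = integer(),
      exon_structure = list()
    )
    class(out) <- c("circ_seq_tbl", class(out))
    return(out)
  }
  rows <- purrr::pmap(
    circles[required],
    function(circ_id, chrom, start, end, strand) {
      assemble_one_circle(circ_id, chrom, start, end, strand, genome, models,
                          fallback_genomic)
    }
  )
  out <- dplyr::bind_rows(rows)
  class(out) <- c("circ_seq_tbl", class(out))
  out
}

assemble_one_circle <- function(circ_id, chrom, start, end, strand, genome,
                                models, fallback_genomic) {
  if (!chrom %in% names(genome)) {
    stop("chromosome '", chrom, "' absent from genome", call. = FALSE)
  }
  chrom_seq <- genome[[chrom]]
  if (end > nchar(chrom_seq)) {
    stop(circ_id, ": junction end exceeds chromosome length", call. = FALSE)
  }
  tx <- if (is.null(models)) NULL else {
    pick_transcript(models, chrom, start, end, strand)
  }
  if (is.null(tx)) {
    if (!fallback_genomic) {
      stop(circ_id, ": junction does not match annotated exon boundaries ",
           "and genomic fallback is disabled", call. = FALSE)
    }
    warning(circ_id, ": no transcript matches both junction boundaries; ",
            "using unspliced genomic span", call. = FALSE)
    exons <- tibble::tibble(exon_start = start, exon_end = end)
    tx_id <- NA_character_
  } else {
    exons <- tx[, c("exon_start", "exon_end")]
    tx_id <- tx$transcript_id[1]
  }
  # concatenate in genomic order; transcript orientation = revcomp for minus
  pieces <- substring(chrom_seq, exons$exon_start + 1L, exons$exon_end)
  seq <- toupper(paste(pieces, collapse = ""))
  if (strand == "-") seq <- revcomp(seq)
  tibble::tibble(
    circ_id = circ_id, chrom = chrom, start = start, end = end,
    strand = strand, transcript_id = tx_id, n_exons = nrow(exons),
    sequence = seq, length = nchar(seq),
    exon_structure = list(exons)
  )
}

# Transcripts qualify when one exon starts exactly at the junction start and
# one exon ends exactly at the junction end (same chrom/strand); returns the
# included exons of the winning transcript, sorted by genomic coordinate.
pick_transcript <- function(models, chrom, start, end, strand) {
  cand <- models |>
    dplyr::filter(.data$chrom == .env$chrom, .data$strand == .env$strand)
  if (nrow(cand) == 0) return(NULL)
  per_tx <- cand |>
    dplyr::summarise(
      hit_start = any(.data$exon_start == .env$start),
      hit_end = any(.data$exon_end == .env$end),
      n_inside = sum(.data$exon_start >= .env$start &
                       .data$exon_end <= .env$end),
      .by = "transcript_id"
    ) |>
    dplyr::filter(.data$hit_start, .data$hit_end) |>
    dplyr::arrange(dplyr::desc(.data$n_inside), .data$transcript_id)
  if (nrow(per_tx) == 0) return(NULL)
  winner <- per_tx$transcript_id[1]
  cand |>
    dplyr::filter(.data$transcript_id == winner,
                  .data$exon_start >= .env$start,
                  .data$exon_end <= .env$end) |>
    dplyr::arrange(.data$exon_start)
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Reverse complements, uppercase.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write circle sequences as FASTA
#'
#' Headers follow `circ_id|chrom:start-end(strand)|L=<nt>`.
#'
#' @param circ_seqs Output of [assemble_circ_sequence()].
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_circ_fasta <- function(circ_seqs, path) {
  headers <- sprintf("%s|%s:%d-%d(%s)|L=%d",
                     circ_seqs$circ_id, circ_seqs$chrom, circ_seqs$start,
                     circ_seqs$end, circ_seqs$strand, circ_seqs$length)
  write_fasta(setNames(circ_seqs$sequence, headers), path, type = "dna")
}
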