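#' Predict open reading frames on circular RNA sequences
#'
#' Translation on a covalently closed circle is defined on the infinite
#' repetition of the circle sequence: from every occurrence of a start codon
#' at circle offsets `0..L-1` (occurrences spanning the back-splice junction
#' included), codons are read until the first in-frame stop. The reading
#' frame at the start offset recurs after `P` passes around the circle
#' (`P = 1` when `L mod 3 = 0`, else `P = 3`), so scanning `P*L` nt from the
#' start decides every ORF: a stop inside that window terminates the ORF; no
#' stop means the ORF is periodic ("infinite") — it is reported with
#' `termination = "none"` and its protein truncated at `P*L` nt.
#'
#' This is what makes rolling-circle translation representable: when `L` is
#' not a multiple of 3, read-through past the junction shifts frame each
#' pass, and a single ORF can encode a protein longer than one pass of the
#' circle (a 322-nt circle can encode a 161-aa protein).
#'
#' Nested ORFs (in-frame downstream starts) share their stop codon and are
#' all reported, linked by a common `stop_id`. Codons containing `N`
#' translate to `X` and never count as stop.
#'
#' @param circ_seqs A [assemble_circ_sequence()] tibble, or any tibble with
#'   `circ_id` and `sequence` columns (`length` is recomputed if absent).
#' @param min_aa Minimum protein length in residues to report. The default
#'   of 20 reflects a typical floor for an MS-detectable product.
#' @param start_codons Candidate start codons (default ATG only).
#' @param genetic_code Named codon table; defaults to the standard code
#'   (`Biostrings::GENETIC_CODE`).
#' @return A tibble of class `circ_orf_tbl`: `circ_id`, `orf_id`,
#'   `start_offset` (0-based nt of the initiator A on the circle),
#'   `coding_length` (nt, stop excluded; always `3 * nchar(protein)`),
#'   `protein`, `passes` (junction crossings by coding codons),
#'   `junction_spanning`, `termination` (`"stop"`/`"none"`), `stop_id`,
#'   `circle_length`.
#' @examples
#' circ <- tibble::tibble(circ_id = "toy", sequence = "ATGTAA")
#' find_circular_orfs(circ, min_aa = 1)
#' @export
find_circular_orfs <- function(circ_seqs, min_aa = 20L,
                               start_codons = "ATG",
                               genetic_code = Biostrings::GENETIC_CODE) {
  required <- c("circ_id", "sequence")
  missing <- setdiff(required, names(circ_seqs))
  if (length(missing) > 0) {
    stop("circ_seqs lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  start_codons <- toupper(start_codons)
  if (nrow(circ_seqs) == 0) {
    out <- empty_orf_tbl()
    class(out) <- c("circ_orf_tbl", class(out))
    return(out)
  }
  out <- purrr::map2(
    circ_seqs$circ_id, toupper(circ_seqs$sequence),
    ~ orfs_one_circle(.x, .y, min_aa, start_codons, genetic_code)
  ) |>
    dplyr::bind_rows()
  class(out) <- c("circ_orf_tbl", class(out))
  out
}

orfs_one_circle <- function(circ_id, seq, min_aa, start_codons, genetic_code) {
  L <- nchar(seq)
  if (L < 3) stop(circ_id, ": circle length must be >= 3", call. = FALSE)
  if (grepl("[^ACGTN]", seq)) {
    stop(circ_id, ": sequence contains characters outside ACGTN",
         call. = FALSE)
  }
  P <- if (L %% 3 == 0) 1L else 3L
  lin <- strrep(seq, P + 1L)          # covers P*L nt from any start in 0..L-1
  wrapped <- substring(paste0(seq, substr(seq, 1, 2)), 1:L, 3:(L + 2))
  starts0 <- which(wrapped %in% start_codons) - 1L   # 0-based circle offsets
  if (length(starts0) == 0) return(empty_orf_tbl())

  n_codons <- (P * L) %/% 3L
  rows <- purrr::map(starts0, function(s0) {
    pos <- s0 + 3L * (0:(n_codons - 1L)) + 1L        # 1-based codon starts
    codons <- substring(lin, pos, pos + 2L)
    aa <- unname(genetic_code[codons])
    aa[is.na(aa)] <- "X"                             # N-containing codons
    stop_at <- which(aa == "*")[1]
    if (is.na(stop_at)) {
      protein <- paste(aa, collapse = "")
      termination <- "none"
      stop_circle_offset <- NA_integer_
    } else {
      protein <- paste(aa[seq_len(stop_at - 1L)], collapse = "")
      termination <- "stop"
      stop_circle_offset <- (s0 + 3L * (stop_at - 1L)) %% L
    }
    coding_length <- 3L * nchar(protein)
    tibble::tibble(
      circ_id = circ_id, start_offset = s0, coding_length = coding_length,
      protein = protein,
      passes = junction_crossings(s0, coding_length, L),
      junction_spanning = s0 + coding_length > L,
      termination = termination,
      stop_id = ifelse(is.na(stop_circle_offset), NA_character_,
                       sprintf("%s:stop@%d", circ_id, stop_circle_offset)),
      circle_length = L
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::filter(nchar(.data$protein) >= min_aa) |>
    dplyr::arrange(.data$start_offset)
  if (nrow(out) > 0) {
    out <- dplyr::mutate(out,
      orf_id = sprintf("%s|orf%d", .data$circ_id, dplyr::row_number()),
      .after = "circ_id")
  } else {
    out <- dplyr::mutate(out, orf_id = character(), .after = "circ_id")
  }
  out
}

empty_orf_tbl <- function() {
  tibble::tibble(
    circ_id = character(), orf_id = character(), start_offset = integer(),
    coding_length = integer(), protein = character(), passes = integer(),
    junction_spanning = logical(), termination = character(),
    stop_id = character(), circle_length = integer()
  )
}

# Number of times the coding region (stop excluded) crosses circle offset 0:
# boundaries k*L with coding nt on both sides, i.e. start < k*L < start+len.
junction_crossings <- function(start, len, L) {
  if (len == 0L) return(0L)
  as.integer((start + len - 1L) %/% L - start %/% L)
}

#' Classify junction-spanning ORFs and locate their crossings
#'
#' Recomputes, from first principles, whether each ORF's coding region (stop
#' codon excluded — a deliberate convention, since either choice is
#' defensible) leaves the first pass of the circle, and which protein
#' residues sit on a codon that straddles the back-splice junction.
#'
#' @param orfs A [find_circular_orfs()] tibble.
#' @return The input with `junction_spanning` and `passes` recomputed and a
#'   `crossing_residues` list column (1-based aa positions whose codon
#'   contains the junction).
#' @export
classify_junction_spanning <- function(orfs) {
  orfs |>
    dplyr::mutate(
      junction_spanning = .data$start_offset + .data$coding_length >
        .data$circle_length,
      passes = purrr::pmap_int(
        list(.data$start_offset, .data$coding_length, .data$circle_length),
        junction_crossings
      ),
      crossing_residues = purrr::pmap(
        list(.data$start_offset, .data$coding_length, .data$circle_length),
        function(s, len, L) {
          if (len == 0L) return(integer())
          ks <- seq_len((s + len - 1L) %/% L)
          # aa whose codon contains both k*L - 1 and k*L (0-based line coords)
          j <- (ks * L - 1L - s) %/% 3L
          sort(unique(j[j >= 0 & 3L * j + 2L >= ks * L - s &
                          3L * j <= ks * L - 1L - s] + 1L))
        }
      )
    )
}

#' Select ORFs by reporting policy
#'
#' `"all"` keeps every predicted ORF. `"longest_junction_spanning"` keeps,
#' per circle, the single longest junction-spanning stop-terminated ORF
#' (ties: smallest start offset) — the reporting policy matching published
#' translatable-circRNA screens, where junction-crossing products are the
#' evidence class of interest.
#'
#' @param orfs A [find_circular_orfs()] tibble.
#' @param policy Reporting policy.
#' @param include_infinite Keep ORFs with `termination = "none"`. Off by
#'   default: peptide databases should contain terminating products.
#' @return Filtered ORF tibble.
#' @export
select_orfs <- function(orfs,
                        policy = c("all", "longest_junction_spanning"),
                        include_infinite = FALSE) {
  policy <- match.arg(policy)
  out <- orfs
  if (!include_infinite) out <- dplyr::filter(out, .data$termination == "stop")
  if (policy == "longest_junction_spanning") {
    out <- out |>
      dplyr::filter(.data$junction_spanning) |>
      dplyr::arrange(dplyr::desc(.data$coding_length), .data$start_offset) |>
      dplyr::distinct(.data$circ_id, .keep_all = TRUE) |>
      dplyr::arrange(.data$circ_id)
  }
  out
}

#' Write predicted ORF proteins as FASTA (+ TSV summary)
#'
#' Headers follow
#' `circ_id|orf<k>|start=<nt>|len_aa=<n>|passes=<p>|span=<bool>|term=<stop|none>`.
#'
#' @param orfs A [find_circular_orfs()] tibble.
#' @param path Output FASTA path; a `.tsv` summary is written alongside.
#' @return The path, invisibly.
#' @export
write_orf_fasta <- function(orfs, path) {
  headers <- sprintf("%s|start=%d|len_aa=%d|passes=%d|span=%s|term=%s",
                     orfs$orf_id, orfs$start_offset, nchar(orfs$protein),
                     orfs$passes, tolower(orfs$junction_spanning),
                     orfs$termination)
  write_fasta(setNames(orfs$protein, headers), path, type = "protein")
  readr::write_tsv(
    orfs[, c("circ_id", "orf_id", "start_offset", "coding_length", "passes",
             "junction_spanning", "termination")],
    paste0(sub("\\.fa(sta)?$", "", path), ".tsv"), progress = FALSE
  )
  invisible(path)
}
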