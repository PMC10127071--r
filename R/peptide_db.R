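#' In-silico proteolytic digestion of a single protein
#'
#' Trypsin rule: cleave C-terminal of K or R except when the following
#' residue is proline. All products with up to `max_missed` internal
#' uncleaved sites are enumerated with their positions.
#'
#' @param protein Amino-acid string over the 20-letter alphabet plus `X`.
#' @param enzyme Only `"trypsin"` is implemented.
#' @param max_missed Maximum internal missed cleavage sites per peptide.
#' @return A tibble with `peptide`, `start_aa` (0-based position in the
#'   protein), `n_aa`, `missed_cleavages`. Empty protein gives zero rows.
#' @examples
#' digest("MKRAPK", max_missed = 0)$peptide   # "MK" "R" "APK"
#' @export
digest <- function(protein, enzyme = "trypsin", max_missed = 2L) {
  if (enzyme != "trypsin") stop("unsupported enzyme: ", enzyme, call. = FALSE)
  n <- nchar(protein)
  if (n == 0) {
    return(tibble::tibble(peptide = character(), start_aa = integer(),
                          n_aa = integer(), missed_cleavages = integer()))
  }
  res <- strsplit(protein, "")[[1]]
  # cleavage after residue i when res[i] in {K,R} and res[i+1] != P;
  # the C-terminus itself is not a site
  cut_after <- if (n >= 2) {
    which(res[-n] %in% c("K", "R") & res[-1] != "P")
  } else {
    integer()
  }
  bounds <- c(0L, cut_after, n)                   # segment boundaries
  n_seg <- length(bounds) - 1L
  out <- vector("list", n_seg)
  for (i in seq_len(n_seg)) {
    j_max <- min(n_seg, i + max_missed)
    js <- i:j_max
    out[[i]] <- tibble::tibble(
      peptide = substring(protein, bounds[i] + 1L, bounds[js + 1L]),
      start_aa = bounds[i],
      n_aa = bounds[js + 1L] - bounds[i],
      missed_cleavages = js - i
    )
  }
  dplyr::bind_rows(out)
}

#' Digest predicted circRNA ORF proteins into candidate peptides
#'
#' Applies [digest()] to every ORF and annotates each peptide with its
#' parent ORF and whether its codon span crosses the back-splice junction —
#' the property that makes a peptide impossible to derive from the linear
#' host transcript.
#'
#' @param orfs A [find_circular_orfs()] tibble.
#' @param max_missed Maximum missed cleavages (see [digest()]).
#' @param include_infinite Also digest ORFs with `termination = "none"`.
#'   Off by default: a truncated periodic product is not a real proteoform.
#' @return A tibble of class `circ_peptide_tbl`: `peptide`, `circ_id`,
#'   `orf_id`, `start_aa`, `n_aa`, `missed_cleavages`, `spans_junction`.
#' @export
digest_peptides <- function(orfs, max_missed = 2L, include_infinite = FALSE) {
  if (!include_infinite) {
    orfs <- dplyr::filter(orfs, .data$termination == "stop")
  }
  rows <- purrr::pmap(
    orfs[c("circ_id", "orf_id", "protein", "start_offset", "circle_length")],
    function(circ_id, orf_id, protein, start_offset, circle_length) {
      peps <- digest(protein, max_missed = max_missed)
      if (nrow(peps) == 0) return(NULL)
      nt_start <- start_offset + 3L * peps$start_aa
      peps |>
        dplyr::mutate(
          circ_id = circ_id, orf_id = orf_id,
          spans_junction = purrr::map2_lgl(
            nt_start, 3L * peps$n_aa,
            ~ junction_crossings(.x, .y, circle_length) > 0L
          )
        )
    }
  )
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(peptide = character(), start_aa = integer(),
                          n_aa = integer(), missed_cleavages = integer(),
                          circ_id = character(), orf_id = character(),
                          spans_junction = logical())
  }
  out <- dplyr::relocate(out, "peptide", "circ_id", "orf_id")
  class(out) <- c("circ_peptide_tbl", class(out))
  out
}

#' Collapse isobaric leucine/isoleucine to one symbol
#'
#' Standard MS cannot distinguish Leu from Ile; uniqueness claims should
#' treat them as identical.
#'
#' @param x Amino-acid strings.
#' @return Strings with `I` and `L` both written as `J`.
#' @export
collapse_il <- function(x) {
  chartr("IL", "JJ", x)
}

#' Filter candidate peptides against a reference proteome
#'
#' A peptide is removed when its sequence occurs as a substring of any
#' reference protein — substring matching (rather than comparing tryptic
#' peptide sets) is deliberately strict, so semi-tryptic products of
#' reference proteins can never masquerade as circRNA-unique evidence.
#' With `il_equivalence = TRUE` (default) I and L are collapsed on both
#' sides before matching. Peptides outside `[min_len, max_len]` residues are
#' dropped as outside the MS-observable range.
#'
#' @param peptides A [digest_peptides()] tibble.
#' @param reference_proteome Named character vector of reference protein
#'   sequences ([read_fasta()] with `type = "protein"`).
#' @param il_equivalence Treat I and L as identical for matching.
#' @param min_len,max_len Peptide length bounds in residues.
#' @return The surviving peptides with `unique_vs_reference = TRUE`.
#' @export
filter_unique_peptides <- function(peptides, reference_proteome,
                                   il_equivalence = TRUE,
                                   min_len = 7L, max_len = 52L) {
  out <- dplyr::filter(peptides, .data$n_aa >= min_len, .data$n_aa <= max_len)
  if (nrow(out) == 0) {
    return(dplyr::mutate(out, unique_vs_reference = logical()))
  }
  if (length(reference_proteome) == 0) {
    return(dplyr::mutate(out, unique_vs_reference = TRUE))
  }
  # "|" never occurs in a peptide, so one concatenated haystack suffices and
  # no match can bridge two reference proteins
  haystack <- paste(unname(reference_proteome), collapse = "|")
  needles <- out$peptide
  if (il_equivalence) {
    haystack <- collapse_il(haystack)
    needles <- collapse_il(needles)
  }
  in_ref <- vapply(needles, function(p) grepl(p, haystack, fixed = TRUE),
                   logical(1), USE.NAMES = FALSE)
  out <- out[!in_ref, , drop = FALSE]
  dplyr::mutate(out, unique_vs_reference = TRUE)
}

#' Write the combined proteogenomic search database
#'
#' Emits the reference proteome unchanged followed by one entry per
#' predicted circRNA ORF, whose accessions carry a `CIRC|` prefix so that
#' downstream tools can partition hits into reference vs circRNA-derived.
#' Output is deterministic: same inputs, byte-identical file.
#'
#' @param orfs A [find_circular_orfs()] tibble.
#' @param reference_proteome Named character vector of reference proteins.
#' @param path Output FASTA path.
#' @param include_infinite Include non-terminating ORFs.
#' @return The path, invisibly.
#' @export
write_search_database <- function(orfs, reference_proteome, path,
                                  include_infinite = FALSE) {
  if (!include_infinite) {
    orfs <- dplyr::filter(orfs, .data$termination == "stop")
  }
  if (any(startsWith(names(reference_proteome), "CIRC|"))) {
    stop("reference proteome contains accessions with the reserved ",
         "'CIRC|' prefix", call. = FALSE)
  }
  circ_acc <- sprintf("CIRC|%s|start=%d|len_aa=%d|passes=%d|span=%s|term=%s",
                      orfs$orf_id, orfs$start_offset, nchar(orfs$protein),
                      orfs$passes, tolower(orfs$junction_spanning),
                      orfs$termination)
  records <- c(reference_proteome, setNames(orfs$protein, circ_acc))
  write_fasta(records, path, type = "protein")
}

#' Write the peptide report
#'
#' @param peptides A [filter_unique_peptides()] (or [digest_peptides()])
#'   tibble.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_peptide_report <- function(peptides, path) {
  cols <- intersect(c("peptide", "circ_id", "orf_id", "start_aa",
                      "missed_cleavages", "spans_junction",
                      "unique_vs_reference"), names(peptides))
  readr::write_tsv(peptides[, cols], path, progress = FALSE)
  invisible(path)
}
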