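#' Read a peptide-spectrum-match (PSM) table
#'
#' Parses a search-engine PSM export (e.g. a MaxQuant evidence/msms table cut
#' down to the relevant columns) into the package's PSM schema. Column names
#' are configurable through `column_map` so different engines' exports can be
#' consumed without editing the file.
#'
#' Normalization applied per row:
#' * peptide sequences are uppercased;
#' * rows with an empty peptide are dropped and counted;
#' * rows whose peptide contains characters outside the 20 amino acids + `X`
#'   are rejected with a warning giving the reason;
#' * q-values outside \[0, 1\] are rejected.
#'
#' @param path Path to a TSV with a header.
#' @param column_map Named list mapping schema fields (`peptide`, and
#'   optionally `accessions`, `q_value`, `score`) to column names in the file.
#' @return A tibble with columns `peptide`, `accessions` (semicolon-joined
#'   string or `NA`), `q_value`, `score`, plus attribute `n_rejected`.
#' @export
read_psm_table <- function(path,
                           column_map = list(peptide = "peptide",
                                             accessions = "accessions",
                                             q_value = "q_value",
                                             score = "score")) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  pep_col <- column_map$peptide %||% "peptide"
  if (!pep_col %in% names(raw)) {
    stop("PSM table ", path, " lacks peptide column '", pep_col, "'",
         call. = FALSE)
  }
  grab <- function(field) {
    col <- column_map[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  out <- tibble::tibble(
    peptide = toupper(trimws(raw[[pep_col]] %||% character())),
    accessions = grab("accessions"),
    q_value = suppressWarnings(as.numeric(grab("q_value"))),
    score = suppressWarnings(as.numeric(grab("score")))
  )
  empty <- is.na(out$peptide) | out$peptide == ""
  bad_seq <- !empty & grepl("[^ACDEFGHIKLMNPQRSTVWYX]", out$peptide)
  bad_q <- !is.na(out$q_value) & (out$q_value < 0 | out$q_value > 1)
  reject <- empty | bad_seq | bad_q
  if (any(reject)) {
    reasons <- dplyr::case_when(
      empty ~ "empty peptide",
      bad_seq ~ "non-amino-acid characters",
      bad_q ~ "q-value outside [0,1]",
      .default = NA_character_
    )[reject]
    warning(sprintf("%s: dropped %d PSM row(s): %s", path, sum(reject),
                    paste(sprintf("line %d (%s)",
                                  which(reject) + 1L, reasons),
                          collapse = "; ")),
            call. = FALSE)
  }
  out <- out[!reject, , drop = FALSE]
  attr(out, "n_rejected") <- sum(reject)
  out
}

#' Read a PRM transition-area report
#'
#' Expects the Skyline-exportable layout: one row per
#' (peptide, sample, fragment) with light (endogenous) and heavy
#' (spiked synthetic) peak areas.
#'
#' @param path Path to a CSV with header columns `peptide`, `sample`,
#'   `fragment`, `light_area`, `heavy_area`.
#' @return A tibble with those columns, areas numeric.
#' @export
read_prm_table <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    peptide = "c", sample = "c", fragment = "c",
    light_area = "d", heavy_area = "d"
  ), progress = FALSE, show_col_types = FALSE)
  required <- c("peptide", "sample", "fragment", "light_area", "heavy_area")
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    stop("PRM table ", path, " lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out
}
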