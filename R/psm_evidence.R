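#' Map peptide-spectrum matches to circRNAs
#'
#' Cross-verifies predicted circRNA translation with MS evidence: PSMs
#' passing the q-value threshold whose peptide matches (under the same I/L
#' equivalence used to build the database) a circRNA-unique peptide are
#' attached to that circle, and circles with at least one such peptide are
#' nominated as translatable.
#'
#' Every nomination is `flagged_for_review = TRUE`: the manual-curation step
#' of published screens is represented here as a machine-readable review
#' report ([write_evidence_report()]), never as silent auto-acceptance. A
#' PSM whose peptide matches the unique set of more than one circle is
#' attached to all of them with `ambiguous = TRUE`. PSMs without a reported
#' q-value are treated as passing (the threshold can only be applied where
#' the engine reported one); PSMs matching only reference proteins
#' contribute nothing by construction, since they cannot match a peptide
#' that survived [filter_unique_peptides()].
#'
#' @param psms A [read_psm_table()] tibble.
#' @param peptide_db A [filter_unique_peptides()] tibble (circRNA-unique
#'   peptides only).
#' @param q_threshold Maximum q-value (default 0.01, standard 1% FDR).
#' @param il_equivalence Match peptides with I/L collapsed; must mirror the
#'   setting used to build `peptide_db`.
#' @return A tibble of class `circ_evidence_tbl`, one row per translatable
#'   circle, sorted by supporting-spectrum count: `circ_id`,
#'   `n_unique_peptides`, `n_spectra`, `best_q_value`, `n_junction_spanning`,
#'   `ambiguous`, `flagged_for_review`, and an `evidence` list column with
#'   the per-PSM detail.
#' @export
map_psms_to_circrnas <- function(psms, peptide_db, q_threshold = 0.01,
                                 il_equivalence = TRUE) {
  if (nrow(peptide_db) > 0 && !"unique_vs_reference" %in% names(peptide_db)) {
    stop("peptide_db must carry uniqueness flags ",
         "(run filter_unique_peptides() first)", call. = FALSE)
  }
  db <- dplyr::filter(peptide_db, .data$unique_vs_reference)
  passing <- dplyr::filter(psms, is.na(.data$q_value) |
                             .data$q_value <= q_threshold)
  if (nrow(passing) == 0 || nrow(db) == 0) return(empty_evidence_tbl())

  key <- if (il_equivalence) collapse_il else identity
  hits <- passing |>
    dplyr::mutate(.pep_key = key(.data$peptide), .spectrum = dplyr::row_number()) |>
    dplyr::inner_join(
      db |>
        dplyr::mutate(.pep_key = key(.data$peptide)) |>
        dplyr::select(".pep_key", db_peptide = "peptide", "circ_id",
                      "orf_id", "spans_junction"),
      by = ".pep_key", relationship = "many-to-many"
    )
  if (nrow(hits) == 0) return(empty_evidence_tbl())

  hits <- hits |>
    dplyr::mutate(
      n_circles_matched = dplyr::n_distinct(.data$circ_id),
      .by = ".pep_key"
    )
  out <- hits |>
    dplyr::group_by(.data$circ_id) |>
    dplyr::summarise(
      n_unique_peptides = dplyr::n_distinct(.data$.pep_key),
      n_spectra = dplyr::n_distinct(.data$.spectrum),
      best_q_value = suppressWarnings(min(.data$q_value, na.rm = TRUE)),
      n_junction_spanning = dplyr::n_distinct(.data$.pep_key[.data$spans_junction]),
      ambiguous = any(.data$n_circles_matched > 1L),
      evidence = list({
        g <- dplyr::pick(dplyr::everything())
        tibble::tibble(
          peptide = g$peptide, db_peptide = g$db_peptide, orf_id = g$orf_id,
          q_value = g$q_value, spans_junction = g$spans_junction,
          shared_across_circles = g$n_circles_matched > 1L
        )
      })
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      best_q_value = ifelse(is.finite(.data$best_q_value),
                            .data$best_q_value, NA_real_),
      flagged_for_review = TRUE
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_spectra), .data$circ_id) |>
    dplyr::relocate("evidence", .after = dplyr::last_col())
  class(out) <- c("circ_evidence_tbl", class(out))
  out
}

empty_evidence_tbl <- function() {
  out <- tibble::tibble(
    circ_id = character(), n_unique_peptides = integer(),
    n_spectra = integer(), best_q_value = double(),
    n_junction_spanning = integer(), ambiguous = logical(),
    flagged_for_review = logical(), evidence = list()
  )
  class(out) <- c("circ_evidence_tbl", class(out))
  out
}

#' Write the translatable-circRNA report and evidence detail table
#'
#' Two TSVs for human review: `<path>` with one row per nominated circle and
#' `<path>.evidence.tsv` with one row per supporting PSM (peptide, q-value,
#' parent ORF, junction-span flag) — the machine-readable stand-in for
#' manual curation of MS hits.
#'
#' @param evidence A [map_psms_to_circrnas()] tibble.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_evidence_report <- function(evidence, path) {
  readr::write_tsv(
    dplyr::select(as.data.frame(evidence), -"evidence"), path,
    progress = FALSE
  )
  detail <- evidence |>
    dplyr::select("circ_id", "evidence") |>
    tidyr::unnest("evidence")
  readr::write_tsv(detail, paste0(path, ".evidence.tsv"), progress = FALSE)
  invisible(path)
}
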