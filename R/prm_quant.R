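#' Compute PRM light/heavy ratios per peptide and sample
#'
#' Parallel reaction monitoring quantifies an endogenous ("light") peptide
#' against a spiked heavy-isotope-labelled synthetic standard. Relative
#' abundance per (peptide, sample) is the ratio of summed transition peak
#' areas, endogenous over heavy — the ratio-of-sums convention of targeted
#' proteomics software, which is robust to a single weak transition (as
#' opposed to averaging per-transition ratios).
#'
#' Transitions present in only one channel (missing or non-finite area in
#' the other) are dropped pairwise with a warning. Fewer than
#' `min_transitions` usable transitions for a precursor is an error, as is a
#' total heavy area of zero (the ratio is undefined without the standard).
#'
#' @param transitions A [read_prm_table()] tibble: one row per
#'   (peptide, sample, fragment) with `light_area` and `heavy_area`.
#' @param min_transitions Minimum transitions per precursor; the accepted
#'   floor for reliable PRM quantification is 3.
#' @return A tibble of class `prm_ratio_tbl`: `peptide`, `sample`,
#'   `n_transitions`, `light_total`, `heavy_total`, `ratio`.
#' @examples
#' tr <- tibble::tibble(
#'   peptide = "PEPTIDEK", sample = "s1", fragment = c("y4", "y5", "y6"),
#'   light_area = c(100, 200, 300), heavy_area = c(200, 400, 600)
#' )
#' compute_prm_ratios(tr)$ratio  # 0.5
#' @export
compute_prm_ratios <- function(transitions, min_transitions = 3L) {
  ok <- is.finite(transitions$light_area) & is.finite(transitions$heavy_area) &
    transitions$light_area >= 0 & transitions$heavy_area >= 0
  if (any(!ok)) {
    warning(sum(!ok), " transition(s) present in only one channel were ",
            "dropped pairwise", call. = FALSE)
    transitions <- transitions[ok, , drop = FALSE]
  }
  out <- transitions |>
    dplyr::summarise(
      n_transitions = dplyr::n_distinct(.data$fragment),
      light_total = sum(.data$light_area),
      heavy_total = sum(.data$heavy_area),
      .by = c("peptide", "sample")
    )
  short <- out$n_transitions < min_transitions
  if (any(short)) {
    stop("fewer than ", min_transitions, " transitions for precursor(s): ",
         paste(sprintf("%s/%s (%d)", out$peptide[short], out$sample[short],
                       out$n_transitions[short]), collapse = ", "),
         "; at least ", min_transitions,
         " transitions per precursor are required", call. = FALSE)
  }
  zero_heavy <- out$heavy_total == 0
  if (any(zero_heavy)) {
    stop("total heavy area is zero for precursor(s): ",
         paste(sprintf("%s/%s", out$peptide[zero_heavy],
                       out$sample[zero_heavy]), collapse = ", "),
         "; ratio undefined", call. = FALSE)
  }
  out <- dplyr::mutate(out, ratio = .data$light_total / .data$heavy_total) |>
    dplyr::arrange(.data$peptide, .data$sample)
  class(out) <- c("prm_ratio_tbl", class(out))
  out
}

#' Compare PRM ratios between two sample groups
#'
#' Per peptide, computes the fold change `mean(group_a) / mean(group_b)` and
#' a two-tailed unpaired t-test p-value (Welch by default; set
#' `var_equal = TRUE` for the pooled-variance variant).
#'
#' Degenerate cases are reported, not hidden: a group with fewer than two
#' samples yields the fold change with `p_value = NA`; a zero group-b mean
#' yields an undefined fold change with `degenerate = TRUE`.
#'
#' @param ratios A [compute_prm_ratios()] tibble.
#' @param group_a,group_b Character vectors of sample ids.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return An object of class `prm_comparison`; see [tidy.prm_comparison()]
#'   for the per-peptide table and [glance.prm_comparison()] for the
#'   one-row summary.
#' @export
compare_conditions <- function(ratios, group_a, group_b, var_equal = FALSE) {
  unknown <- setdiff(c(group_a, group_b), unique(ratios$sample))
  if (length(unknown) > 0) {
    stop("sample(s) not present in ratios: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  res <- ratios |>
    dplyr::filter(.data$sample %in% c(group_a, group_b)) |>
    dplyr::group_by(.data$peptide) |>
    dplyr::group_modify(function(g, key) {
      a <- g$ratio[g$sample %in% group_a]
      b <- g$ratio[g$sample %in% group_b]
      mean_a <- mean(a); mean_b <- mean(b)
      fold_change <- if (length(b) == 0 || mean_b == 0) NA_real_ else mean_a / mean_b
      p <- if (length(a) >= 2 && length(b) >= 2 &&
               (stats::sd(a) > 0 || stats::sd(b) > 0)) {
        stats::t.test(a, b, var.equal = var_equal)$p.value
      } else if (length(a) >= 2 && length(b) >= 2) {
        1  # identical constant groups: no evidence of difference
      } else {
        NA_real_
      }
      tibble::tibble(
        n_a = length(a), n_b = length(b), mean_a = mean_a, mean_b = mean_b,
        fold_change = fold_change, p_value = p,
        degenerate = is.na(fold_change)
      )
    }) |>
    dplyr::ungroup()
  structure(
    list(results = res, group_a = group_a, group_b = group_b,
         method = if (var_equal) "pooled two-tailed unpaired t-test"
                  else "Welch two-tailed unpaired t-test"),
    class = "prm_comparison"
  )
}

#' @export
print.prm_comparison <- function(x, ...) {
  cat("PRM group comparison (", x$method, ")\n", sep = "")
  cat("group A:", length(x$group_a), "sample(s); group B:",
      length(x$group_b), "sample(s)\n")
  print(x$results, ...)
  invisible(x)
}

#' Tidy a PRM comparison
#'
#' @param x A [compare_conditions()] object.
#' @param ... Unused.
#' @return Per-peptide tibble: `peptide`, `n_a`, `n_b`, `mean_a`, `mean_b`,
#'   `fold_change`, `p_value`, `degenerate`.
#' @method tidy prm_comparison
#' @export
tidy.prm_comparison <- function(x, ...) {
  x$results
}

#' @rdname tidy.prm_comparison
#' @return For `glance()`, a one-row tibble: number of peptides, number of
#'   testable peptides, number degenerate, method.
#' @method glance prm_comparison
#' @export
glance.prm_comparison <- function(x, ...) {
  tibble::tibble(
    n_peptides = nrow(x$results),
    n_tested = sum(!is.na(x$results$p_value)),
    n_degenerate = sum(x$results$degenerate),
    method = x$method
  )
}

#' Write PRM ratios (and optionally a comparison) as TSV
#'
#' @param ratios A [compute_prm_ratios()] tibble.
#' @param path Output TSV path.
#' @param comparison Optional [compare_conditions()] object; written to
#'   `<path>.comparison.tsv`.
#' @return The path, invisibly.
#' @export
write_prm_report <- function(ratios, path, comparison = NULL) {
  readr::write_tsv(as.data.frame(ratios), path, progress = FALSE)
  if (!is.null(comparison)) {
    readr::write_tsv(tidy(comparison), paste0(path, ".comparison.tsv"),
                     progress = FALSE)
  }
  invisible(path)
}
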