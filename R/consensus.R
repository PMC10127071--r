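#' Build a multi-caller consensus set of circRNAs
#'
#' Groups normalized back-splice junctions across callers and keeps circles
#' supported by at least `min_callers` distinct tools — the "2-of-3" rule
#' widely used to suppress caller-specific artifacts. Strand is part of the
#' identity: sense and antisense circles at the same locus are distinct
#' molecules.
#'
#' With `slack = 0` (the default) junctions are grouped on the exact
#' `(chrom, start, end, strand)` key. With `slack > 0`, junctions on the same
#' chromosome and strand are clustered so that every pair within a cluster
#' differs by at most `slack` nt at both boundaries; the cluster's canonical
#' coordinates are those of its highest-read call (ties: lexicographically
#' smallest `(start, end)`), making output deterministic.
#'
#' Duplicate calls of one circle by one caller collapse to a single
#' supporting vote; their read counts collapse to the maximum before summing
#' across callers.
#'
#' @param calls Junction tibble (rows from any mix of [read_ciri2()] /
#'   [read_caller_bed()] outputs bound together).
#' @param min_callers Minimum number of distinct supporting callers.
#' @param slack Allowed boundary wobble in nt (0 = exact match).
#' @return A tibble of class `circ_consensus_tbl` with columns `circ_id`,
#'   `chrom`, `start`, `end`, `strand`, `n_callers`, `supporting_callers`
#'   (comma-joined), `total_junction_reads`, sorted by `(chrom, start, end)`.
#' @examples
#' calls <- dplyr::bind_rows(
#'   tibble::tibble(chrom = "chr1", start = 99L, end = 200L, strand = "+",
#'                  caller_id = c("ciri2", "find_circ"),
#'                  junction_reads = c(10L, 7L)),
#'   tibble::tibble(chrom = "chr1", start = 500L, end = 900L, strand = "-",
#'                  caller_id = "ciri2", junction_reads = 3L)
#' )
#' build_consensus(calls, min_callers = 2)
#' @export
build_consensus <- function(calls, min_callers = 2L, slack = 0L) {
  if (min_callers < 1L) stop("min_callers must be >= 1", call. = FALSE)
  if (slack < 0L) stop("slack must be >= 0", call. = FALSE)
  if (nrow(calls) == 0) return(empty_consensus())
  validate_bsj_tbl(calls)
  warn_mixed_chrom_naming(calls$chrom)

  calls <- calls |>
    dplyr::mutate(junction_reads = dplyr::coalesce(.data$junction_reads, 0L)) |>
    # a caller re-reporting the same circle collapses to one vote / max reads
    dplyr::summarise(
      junction_reads = max(.data$junction_reads),
      .by = c("chrom", "start", "end", "strand", "caller_id")
    )

  if (slack == 0L) {
    grouped <- calls |>
      dplyr::mutate(.cluster = paste(.data$chrom, .data$start, .data$end,
                                     .data$strand))
  } else {
    grouped <- calls |>
      dplyr::group_by(.data$chrom, .data$strand) |>
      dplyr::group_modify(~ dplyr::mutate(
        .x, .cluster = paste(.y$chrom, .y$strand,
                             slack_clusters(.x$start, .x$end, slack))
      )) |>
      dplyr::ungroup()
  }

  out <- grouped |>
    dplyr::group_by(.data$.cluster) |>
    dplyr::group_modify(function(g, key) {
      # canonical coordinates: highest-read call, then smallest (start, end)
      canon <- g[order(-g$junction_reads, g$start, g$end), ][1, ]
      tibble::tibble(
        chrom = canon$chrom, start = canon$start, end = canon$end,
        strand = canon$strand,
        n_callers = dplyr::n_distinct(g$caller_id),
        supporting_callers = paste(sort(unique(g$caller_id)), collapse = ","),
        total_junction_reads = sum(g$junction_reads)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-".cluster") |>
    dplyr::filter(.data$n_callers >= min_callers) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::mutate(circ_id = circ_key(.data$chrom, .data$start, .data$end,
                                     .data$strand),
                  .before = 1)
  class(out) <- c("circ_consensus_tbl", class(out))
  out
}

empty_consensus <- function() {
  out <- tibble::tibble(
    circ_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), n_callers = integer(),
    supporting_callers = character(), total_junction_reads = integer()
  )
  class(out) <- c("circ_consensus_tbl", class(out))
  out
}

# Greedy deterministic clustering: calls sorted by (start, end, reads desc)
# join the first existing cluster compatible with ALL members (pairwise
# boundary differences <= slack), else open a new one.
slack_clusters <- function(starts, ends, slack) {
  n <- length(starts)
  ord <- order(starts, ends)
  cluster <- integer(n)
  members <- list()
  next_id <- 0L
  for (i in ord) {
    placed <- FALSE
    for (cid in seq_along(members)) {
      m <- members[[cid]]
      if (all(abs(starts[m] - starts[i]) <= slack) &&
          all(abs(ends[m] - ends[i]) <= slack)) {
        members[[cid]] <- c(m, i)
        cluster[i] <- cid
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      next_id <- length(members) + 1L
      members[[next_id]] <- i
      cluster[i] <- next_id
    }
  }
  cluster
}

warn_mixed_chrom_naming <- function(chroms) {
  has_prefix <- grepl("^chr", chroms)
  if (any(has_prefix) && !all(has_prefix)) {
    warning("mixed chromosome naming across callers (some 'chr'-prefixed, ",
            "some not); these will never group together. Use ",
            "strip_chr_prefix = TRUE at parse time if intended.",
            call. = FALSE)
  }
  invisible(NULL)
}

#' Write a consensus set as BED6 (+ caller sidecar)
#'
#' The BED name field is the `circ_id`, the score field the total junction
#' read count. A TSV sidecar (`<path>.callers.tsv`) lists the supporting
#' callers per circle.
#'
#' @param consensus Output of [build_consensus()].
#' @param path Output BED path.
#' @return The path, invisibly.
#' @export
write_consensus_bed <- function(consensus, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   consensus$chrom, consensus$start, consensus$end,
                   consensus$circ_id, consensus$total_junction_reads,
                   consensus$strand)
  writeLines(lines, path)
  readr::write_tsv(
    consensus[, c("circ_id", "n_callers", "supporting_callers")],
    paste0(path, ".callers.tsv"), progress = FALSE
  )
  invisible(path)
}
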