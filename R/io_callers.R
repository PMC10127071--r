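#' Read a CIRI2 result table as back-splice junctions
#'
#' CIRI2 writes a tab-separated table with 1-based inclusive coordinates.
#' Coordinates are converted to the package-wide 0-based half-open convention
#' (`start = circRNA_start - 1`, `end = circRNA_end`). Junction read counts
#' are preserved when the `#junction_reads` (or `junction_reads`) column is
#' present.
#'
#' Malformed rows (non-numeric coordinates, start > end, strand outside
#' `{+,-}`) are skipped with a warning naming the offending line, unless
#' `strict = TRUE`, in which case the first malformed row aborts the parse.
#'
#' @param path Path to a CIRI2 TSV with a header row.
#' @param caller_id Caller label stored in the `caller_id` column.
#' @param strip_chr_prefix Drop a leading `"chr"` from chromosome names.
#'   Off by default: mismatched naming across callers is reported by
#'   [build_consensus()], never silently rewritten.
#' @param strict Abort on the first malformed row instead of skipping it.
#' @return A tibble of junctions with columns `chrom`, `start`, `end`,
#'   `strand`, `caller_id`, `junction_reads`, in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "circRNA_ID\tchr\tcircRNA_start\tcircRNA_end\t#junction_reads\tstrand",
#'   "chr1:100|200\tchr1\t100\t200\t7\t+"
#' ), tf)
#' read_ciri2(tf)
#' @export
read_ciri2 <- function(path, caller_id = "ciri2", strip_chr_prefix = FALSE,
                       strict = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  names(raw) <- sub("^#", "", names(raw))
  required <- c("chr", "circRNA_start", "circRNA_end", "strand")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("CIRI2 table ", path, " lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) return(new_bsj_tbl())
  reads <- if ("junction_reads" %in% names(raw)) {
    suppressWarnings(as.integer(raw$junction_reads))
  } else {
    rep(NA_integer_, nrow(raw))
  }
  start1 <- suppressWarnings(as.integer(raw$circRNA_start))
  end1 <- suppressWarnings(as.integer(raw$circRNA_end))
  # 1-based inclusive -> 0-based half-open
  out <- new_bsj_tbl(
    chrom = raw$chr, start = start1 - 1L, end = end1,
    strand = raw$strand, caller_id = caller_id, junction_reads = reads
  )
  drop_malformed_rows(out, path, strict, source_line = seq_len(nrow(out)) + 1L,
                      strip_chr_prefix = strip_chr_prefix)
}

#' Read a BED-style circRNA caller output as back-splice junctions
#'
#' Both supported dialects use 0-based half-open starts, so no coordinate
#' arithmetic is applied; the dialect decides where junction read counts live:
#' * `"find_circ"`: BED6; column 5 (score) carries the junction read count.
#' * `"circexplorer2"`: BED-like; column 13 (`readNumber`) when present,
#'   otherwise column 5.
#'
#' Rows with `start >= end` or strand `"."` are rejected with a warning
#' (circle orientation is required to assemble a translatable sequence).
#'
#' @param path Path to the caller output (no header).
#' @param dialect One of `"circexplorer2"`, `"find_circ"`.
#' @param caller_id Caller label; defaults to the dialect name.
#' @inheritParams read_ciri2
#' @return A tibble of junctions (see [read_ciri2()] for the schema).
#' @export
read_caller_bed <- function(path, dialect = c("circexplorer2", "find_circ"),
                            caller_id = NULL, strip_chr_prefix = FALSE,
                            strict = FALSE) {
  dialect <- match.arg(dialect)
  caller_id <- caller_id %||% dialect
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0) return(new_bsj_tbl())
  if (ncol(raw) < 6) {
    stop(dialect, " file ", path, " has fewer than 6 columns", call. = FALSE)
  }
  reads_col <- if (dialect == "circexplorer2" && ncol(raw) >= 13) 13L else 5L
  out <- new_bsj_tbl(
    chrom = raw[[1]],
    start = suppressWarnings(as.integer(raw[[2]])),
    end = suppressWarnings(as.integer(raw[[3]])),
    strand = raw[[6]],
    caller_id = caller_id,
    junction_reads = suppressWarnings(as.integer(raw[[reads_col]]))
  )
  drop_malformed_rows(out, path, strict, source_line = seq_len(nrow(out)),
                      strip_chr_prefix = strip_chr_prefix)
}

# Shared row-level validation for junction parsers: flags NA coordinates,
# inverted/degenerate intervals and missing strand, then drops (or aborts on)
# the offenders.
drop_malformed_rows <- function(x, path, strict, source_line,
                                strip_chr_prefix = FALSE) {
  bad <- is.na(x$start) | is.na(x$end) | x$start < 0L | x$start >= x$end |
    !(x$strand %in% c("+", "-"))
  if (any(bad)) {
    msg <- sprintf("%s: %d malformed row(s) at line(s) %s", path, sum(bad),
                   paste(source_line[bad], collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    x <- x[!bad, , drop = FALSE]
  }
  if (strip_chr_prefix) x$chrom <- sub("^chr", "", x$chrom)
  validate_bsj_tbl(x, what = path)
}

#' Convert internal junctions back to a source caller dialect
#'
#' Inverse of the parsers' coordinate normalization; used to emit
#' dialect-native fixtures and to round-trip-test the converters. CIRI2 is
#' 1-based inclusive; the BED dialects are already 0-based half-open.
#'
#' @param junctions Junction tibble in internal coordinates.
#' @param dialect One of `"ciri2"`, `"circexplorer2"`, `"find_circ"`.
#' @return A tibble with `start`/`end` in the dialect's coordinate system.
#' @export
junctions_to_dialect <- function(junctions,
                                 dialect = c("ciri2", "circexplorer2",
                                             "find_circ")) {
  dialect <- match.arg(dialect)
  validate_bsj_tbl(junctions)
  out <- junctions
  if (dialect == "ciri2") {
    out$start <- out$start + 1L
  }
  out
}
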