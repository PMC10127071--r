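#' Read and write FASTA sequence sets
#'
#' Thin wrappers over Biostrings that enforce the package's contracts:
#' record IDs are the header up to the first whitespace, duplicate IDs are an
#' error (naming the duplicates), and write/read round-trips preserve
#' sequence content and order.
#'
#' @param path File path.
#' @param type `"dna"` or `"protein"`.
#' @return For `read_fasta()`, a named character vector of uppercase
#'   sequences (names = IDs). An empty file yields an empty vector.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (file.exists(path) && file.size(path) == 0) {
    return(setNames(character(), character()))
  }
  set <- switch(type,
    dna = Biostrings::readDNAStringSet(path),
    protein = Biostrings::readAAStringSet(path)
  )
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate FASTA IDs in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  setNames(toupper(as.character(set)), ids)
}

#' @rdname read_fasta
#' @param records Named character vector of sequences.
#' @param wrap Line width for the sequence lines.
#' @export
write_fasta <- function(records, path, wrap = 60L, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (is.null(names(records)) && length(records) > 0) {
    stop("records must be named", call. = FALSE)
  }
  dup <- unique(names(records)[duplicated(names(records))])
  if (length(dup) > 0) {
    stop("duplicate FASTA IDs: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  set <- switch(type,
    dna = Biostrings::DNAStringSet(unlist(records) %||% character()),
    protein = Biostrings::AAStringSet(unlist(records) %||% character())
  )
  if (length(records) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  names(set) <- names(records)
  Biostrings::writeXStringSet(set, path, width = as.integer(wrap))
  invisible(path)
}
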