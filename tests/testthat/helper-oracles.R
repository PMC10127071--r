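# Independent oracles and shared fixtures for the suite.

# Linear ORF scanner, deliberately independent of the package's circular
# finder: translates each frame with Biostrings::translate() and reads
# M...* runs off the amino-acid string. Returns all stop-terminated ORFs on
# the LINEAR sequence as (start nt, protein).
linear_orf_scan <- function(seq, min_aa = 1L) {
  n <- nchar(seq)
  out <- list()
  for (f in 0:2) {
    sub <- substr(seq, f + 1L, f + ((n - f) %/% 3L) * 3L)
    if (nchar(sub) < 3) next
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                             no.init.codon = TRUE))
    res <- strsplit(aa, "")[[1]]
    stops <- which(res == "*")
    starts <- which(res == "M")
    for (s in starts) {
      nxt <- stops[stops > s]
      if (length(nxt) == 0) next
      prot <- paste(res[s:(nxt[1] - 1L)], collapse = "")
      if (nchar(prot) < min_aa) next
      out[[length(out) + 1L]] <- list(start = f + 3L * (s - 1L), prot = prot)
    }
  }
  out
}

# (start mod L, protein) pair set from the linear oracle on the (P+1)-fold
# linearization of a circle.
oracle_circular_pairs <- function(seq, min_aa = 1L) {
  L <- nchar(seq)
  P <- if (L %% 3 == 0) 1L else 3L
  lin <- strrep(seq, P + 1L)
  orfs <- linear_orf_scan(lin, min_aa = min_aa)
  unique(vapply(orfs, function(o) {
    paste0(o$start %% L, ":", o$prot)
  }, character(1)))
}

random_circle <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

rotate_seq <- function(seq, r) {
  L <- nchar(seq)
  r <- r %% L
  if (r == 0) return(seq)
  paste0(substring(seq, r + 1L, L), substring(seq, 1L, r))
}

random_junctions <- function(n, callers = c("a", "b", "c")) {
  starts <- sample(0:500, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = starts,
    end = starts + sample(50:300, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    caller_id = sample(callers, n, replace = TRUE),
    junction_reads = sample(1:50, n, replace = TRUE)
  )
}

# Brute-force consensus oracle for slack = 0: exact-key grouping with
# per-caller deduplication, then the k-of-n filter.
brute_force_consensus <- function(calls, min_callers) {
  key <- paste(calls$chrom, calls$start, calls$end, calls$strand)
  keep <- character()
  for (k in unique(key)) {
    sub <- calls[key == k, ]
    if (length(unique(sub$caller_id)) >= min_callers) keep <- c(keep, k)
  }
  sort(keep)
}

# One shared synthetic study per test session (generation is seeded, so the
# content is identical wherever it is built).
sim_fixture_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir) || !file.exists(file.path(dir, "manifest.json"))) {
      dir <<- file.path(tempdir(), "circpep_fixture")
      unlink(dir, recursive = TRUE)
      simulate_circ_study(dir, seed = 101L, n_circles = 30L)
    }
    dir
  }
})

sim_fixture_manifest <- function() {
  jsonlite::read_json(file.path(sim_fixture_dir(), "manifest.json"),
                      simplifyVector = TRUE)
}

sim_fixture_config <- function(out_dir) {
  d <- sim_fixture_dir()
  circpep_config(
    ciri2 = file.path(d, "ciri2.tsv"),
    circexplorer2 = file.path(d, "ce2.bed"),
    find_circ = file.path(d, "findcirc.bed"),
    genome_fasta = file.path(d, "genome.fa"),
    annotation_gtf = file.path(d, "genes.gtf"),
    proteome_fasta = file.path(d, "proteome.fa"),
    psm_table = file.path(d, "psms.tsv"),
    prm_table = file.path(d, "prm.csv"),
    out_dir = out_dir
  )
}
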