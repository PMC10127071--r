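toy_genome <- function(seq, chrom = "chr1") setNames(seq, chrom)

toy_models <- function(starts, ends, strand = "+", chrom = "chr1",
                       tx = "tx1", gene = "g1") {
  tibble::tibble(gene_id = gene, transcript_id = tx, chrom = chrom,
                 strand = strand, exon_start = starts, exon_end = ends)
}

toy_circle <- function(chrom, start, end, strand) {
  tibble::tibble(circ_id = "c1", chrom = chrom, start = start, end = end,
                 strand = strand)
}

test_that("a single-exon plus-strand circle is the exon sequence itself", {
  genome <- toy_genome("ATGTAACCGG")
  models <- toy_models(0L, 6L)
  out <- assemble_circ_sequence(toy_circle("chr1", 0L, 6L, "+"),
                                genome, models)
  expect_equal(out$sequence, "ATGTAA")
  expect_equal(out$length, 6L)
  expect_equal(out$n_exons, 1L)
})

test_that("multi-exon minus-strand circles splice then reverse-complement", {
  # exon1 [10,14) = ATGC, exon2 [20,24) = GGTA; hand oracle:
  # spliced genomic = ATGCGGTA, minus strand circle = revcomp = TACCGCAT
  genome <- toy_genome(paste0(strrep("T", 10), "ATGC", strrep("C", 6),
                              "GGTA", strrep("T", 6)))
  models <- toy_models(c(10L, 20L), c(14L, 24L), strand = "-")
  out <- assemble_circ_sequence(toy_circle("chr1", 10L, 24L, "-"),
                                genome, models)
  expect_equal(out$sequence, "TACCGCAT")
  expect_equal(out$length, 8L)
  expect_equal(out$n_exons, 2L)

  # plus-strand assembly of the same exons is the reverse complement
  models_p <- toy_models(c(10L, 20L), c(14L, 24L), strand = "+")
  out_p <- assemble_circ_sequence(toy_circle("chr1", 10L, 24L, "+"),
                                  genome, models_p)
  expect_equal(out_p$sequence, revcomp(out$sequence))
})

test_that("sequence length equals the sum of contributing exon lengths", {
  d <- sim_fixture_dir()
  genome <- read_fasta(file.path(d, "genome.fa"))
  models <- read_gene_models(file.path(d, "genes.gtf"))
  m <- sim_fixture_manifest()
  circles <- tibble::as_tibble(m$circles)[1:10, ]
  out <- assemble_circ_sequence(
    circles[, c("circ_id", "chrom", "start", "end", "strand")],
    genome, models
  )
  exon_sums <- vapply(out$exon_structure,
                      function(e) sum(e$exon_end - e$exon_start), integer(1))
  expect_equal(nchar(out$sequence), exon_sums)
  # and matches the planted circle sequences exactly
  seqs <- tibble::as_tibble(m$sequences)
  expect_equal(out$sequence,
               seqs$sequence[match(out$circ_id, seqs$circ_id)])
})

test_that("transcript choice prefers exact-boundary matches with most exons", {
  genome <- toy_genome(strrep("ACGT", 30))
  models <- dplyr::bind_rows(
    toy_models(c(0L, 40L), c(12L, 60L), tx = "txB"),
    toy_models(c(0L, 20L, 40L), c(12L, 30L, 60L), tx = "txA")
  )
  out <- assemble_circ_sequence(toy_circle("chr1", 0L, 60L, "+"),
                                genome, models)
  expect_equal(out$transcript_id, "txA")   # 3 exons inside beats 2
  expect_equal(out$n_exons, 3L)
})

test_that("unannotated junctions fall back to the genomic span with a warning", {
  genome <- toy_genome(strrep("ACGT", 10))
  models <- toy_models(0L, 8L)
  expect_warning(
    out <- assemble_circ_sequence(toy_circle("chr1", 1L, 9L, "+"),
                                  genome, models),
    "unspliced genomic span"
  )
  expect_equal(out$sequence, substr(strrep("ACGT", 10), 2, 9))
  expect_true(is.na(out$transcript_id))
  expect_error(
    suppressWarnings(assemble_circ_sequence(
      toy_circle("chr1", 1L, 9L, "+"), genome, models,
      fallback_genomic = FALSE)),
    "fallback"
  )
})

test_that("a chromosome missing from the genome is an error", {
  expect_error(
    assemble_circ_sequence(toy_circle("chrX", 0L, 6L, "+"),
                           toy_genome("ATGTAA"), NULL),
    "absent from genome"
  )
})
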