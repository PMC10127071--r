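make_call <- function(chrom = "chr1", start = 99L, end = 200L, strand = "+",
                      caller = "a", reads = 1L) {
  tibble::tibble(chrom = chrom, start = start, end = end, strand = strand,
                 caller_id = caller, junction_reads = reads)
}

test_that("the k-of-n rule keeps multi-caller circles and drops singletons", {
  calls <- dplyr::bind_rows(
    make_call(caller = "ciri2", reads = 10L),
    make_call(caller = "circexplorer2", reads = 7L),
    make_call(caller = "find_circ", reads = 5L),
    make_call(start = 500L, end = 700L, caller = "ciri2")
  )
  out <- build_consensus(calls, min_callers = 2)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_callers, 3L)
  expect_equal(out$total_junction_reads, 22L)
  expect_equal(out$supporting_callers, "circexplorer2,ciri2,find_circ")

  # duplicate calls from one caller are one vote
  dup <- dplyr::bind_rows(make_call(caller = "a", reads = 3L),
                          make_call(caller = "a", reads = 9L))
  out2 <- build_consensus(dup, min_callers = 2)
  expect_equal(nrow(out2), 0L)
  out3 <- build_consensus(dup, min_callers = 1)
  expect_equal(out3$total_junction_reads, 9L)  # dupes collapse to max
})

test_that("strand and coordinates are both part of the identity key", {
  calls <- dplyr::bind_rows(
    make_call(strand = "+", caller = "a"),
    make_call(strand = "-", caller = "b")
  )
  expect_equal(nrow(build_consensus(calls, min_callers = 2)), 0L)
  expect_equal(nrow(build_consensus(calls, min_callers = 1)), 2L)
})

test_that("consensus equals the brute-force grouping oracle on random calls", {
  set.seed(31)
  for (rep in 1:5) {
    calls <- random_junctions(20)
    for (k in 1:3) {
      got <- build_consensus(calls, min_callers = k)
      expect_equal(sort(paste(got$chrom, got$start, got$end, got$strand)),
                   brute_force_consensus(calls, k))
    }
  }
})

test_that("consensus is invariant to input order and respects edge thresholds", {
  set.seed(37)
  calls <- random_junctions(30)
  a <- build_consensus(calls, min_callers = 2)
  b <- build_consensus(calls[sample(nrow(calls)), ], min_callers = 2)
  expect_equal(a, b)

  # min_callers = 1: deduplicated union; > n callers: empty
  u <- build_consensus(calls, min_callers = 1)
  expect_equal(nrow(u), length(unique(paste(calls$chrom, calls$start,
                                            calls$end, calls$strand))))
  expect_equal(nrow(build_consensus(calls, min_callers = 4)), 0L)
  expect_equal(nrow(build_consensus(calls[0, ], min_callers = 2)), 0L)
})

test_that("slack clustering merges wobbly boundaries deterministically", {
  calls <- dplyr::bind_rows(
    make_call(start = 100L, end = 200L, caller = "a", reads = 3L),
    make_call(start = 102L, end = 199L, caller = "b", reads = 9L),
    make_call(start = 150L, end = 260L, caller = "c", reads = 1L)
  )
  exact <- build_consensus(calls, min_callers = 2, slack = 0)
  expect_equal(nrow(exact), 0L)
  wob <- build_consensus(calls, min_callers = 2, slack = 3)
  expect_equal(nrow(wob), 1L)
  # canonical coordinates come from the highest-read member
  expect_equal(wob$start, 102L)
  expect_equal(wob$end, 199L)
  expect_equal(wob$total_junction_reads, 12L)
})

test_that("mixed chromosome naming across callers is reported", {
  calls <- dplyr::bind_rows(make_call(chrom = "chr1", caller = "a"),
                            make_call(chrom = "1", caller = "b"))
  expect_warning(build_consensus(calls, min_callers = 1), "mixed chromosome")
})

test_that("BED6 output matches the consensus table", {
  set.seed(41)
  cons <- build_consensus(random_junctions(20), min_callers = 1)
  tf <- withr::local_tempfile(fileext = ".bed")
  write_consensus_bed(cons, tf)
  bed <- readr::read_tsv(tf, col_names = FALSE, show_col_types = FALSE)
  expect_equal(nrow(bed), nrow(cons))
  expect_equal(bed$X2, cons$start)
  expect_equal(bed$X6, cons$strand)
  expect_true(file.exists(paste0(tf, ".callers.tsv")))
})
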