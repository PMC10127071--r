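circ_tbl <- function(seqs, ids = paste0("c", seq_along(seqs))) {
  tibble::tibble(circ_id = ids, sequence = seqs)
}

test_that("smallest terminating circle: ATGTAA gives protein M in one pass", {
  out <- find_circular_orfs(circ_tbl("ATGTAA"), min_aa = 1)
  expect_equal(nrow(out), 1L)
  expect_equal(out$protein, "M")
  expect_equal(out$passes, 0L)
  expect_false(out$junction_spanning)
  expect_equal(out$termination, "stop")
  expect_equal(out$coding_length, 3L)
})

test_that("a 10-nt circle finds its stop in the third pass (oracle-checked)", {
  seq <- "ATGGCTGCTA"
  out <- find_circular_orfs(circ_tbl(seq), min_aa = 1)
  hit <- out[out$start_offset == 0, ]
  expect_equal(nchar(hit$protein), 6L)
  expect_true(hit$junction_spanning)
  expect_equal(hit$termination, "stop")
  # independent oracle: linear scan of the (P+1)-fold linearization
  expect_true(paste0("0:", hit$protein) %in% oracle_circular_pairs(seq))
})

test_that("a circle without an in-frame stop is flagged infinite and truncated", {
  out <- find_circular_orfs(circ_tbl("ATGAAAAAA"), min_aa = 1)  # L = 9
  expect_equal(out$termination, "none")
  expect_equal(out$protein, "MKK")          # truncated at P*L = L nt
  expect_equal(out$coding_length, 9L)
  expect_true(is.na(out$stop_id))
})

test_that("rolling-circle structure: 322-nt circle encodes 161 aa across the junction", {
  set.seed(5)
  design <- plant_circle_with_orf("rolling", 322L, 161L)
  out <- find_circular_orfs(circ_tbl(design$sequence), min_aa = 20)
  expect_equal(nrow(out), 1L)
  expect_equal(nchar(out$protein), 161L)
  expect_equal(out$start_offset, 0L)
  expect_true(out$junction_spanning)
  expect_gte(out$passes, 1L)
  expect_equal(out$termination, "stop")
  expect_equal(out$protein, design$protein)
})

test_that("mutating the initiator ATG to CTG removes the ORF", {
  set.seed(6)
  design <- plant_circle_with_orf("rolling", 97L, 40L)
  out <- find_circular_orfs(circ_tbl(design$sequence), min_aa = 10)
  expect_equal(nrow(out), 1L)
  mutated <- paste0("CTG", substring(design$sequence, 4))
  out_mut <- find_circular_orfs(circ_tbl(mutated), min_aa = 10)
  expect_equal(nrow(out_mut), 0L)
})

test_that("stop-terminated ORFs agree with the linear oracle on random circles", {
  set.seed(4242)
  for (i in 1:60) {
    L <- sample(3:240, 1)
    seq <- random_circle(L)
    got <- find_circular_orfs(circ_tbl(seq), min_aa = 1)
    got <- got[got$termination == "stop", ]
    pairs <- sprintf("%d:%s", got$start_offset, got$protein)
    oracle <- oracle_circular_pairs(seq)
    expect_setequal(pairs, oracle)
  }
})

test_that("the protein multiset is invariant under rotation of the circle", {
  set.seed(99)
  for (i in 1:30) {
    L <- sample(12:200, 1)
    seq <- random_circle(L)
    r <- sample(0:(L - 1), 1)
    a <- sort(find_circular_orfs(circ_tbl(seq), min_aa = 1)$protein)
    b <- sort(find_circular_orfs(circ_tbl(rotate_seq(seq, r)), min_aa = 1)$protein)
    expect_identical(a, b)
  }
})

test_that("junction-spanning classification matches the coordinate definition", {
  set.seed(123)
  for (i in 1:50) {
    L <- sample(9:150, 1)
    seq <- random_circle(L)
    orfs <- find_circular_orfs(circ_tbl(seq), min_aa = 1)
    if (nrow(orfs) == 0) next
    cls <- classify_junction_spanning(orfs)
    # brute force from linearized coordinates
    expect_equal(cls$junction_spanning,
                 orfs$start_offset + orfs$coding_length > L)
    covered <- purrr::map2(orfs$start_offset, orfs$coding_length,
                           ~ seq(.x, length.out = .y))
    expect_equal(cls$passes,
                 purrr::map_int(covered, function(p) {
                   if (length(p) == 0) return(0L)
                   sum(seq_len(max(1, max(p) %/% L)) * L > min(p) &
                         seq_len(max(1, max(p) %/% L)) * L <= max(p))
                 }))
  }
})

test_that("nested ORFs in one frame share a stop id", {
  # two in-frame ATGs upstream of one stop: ATG AAA ATG GCC TAA (L = 15)
  out <- find_circular_orfs(circ_tbl("ATGAAAATGGCCTAA"), min_aa = 1)
  expect_equal(nrow(out), 2L)
  expect_equal(dplyr::n_distinct(out$stop_id), 1L)
  expect_equal(sort(nchar(out$protein)), c(2L, 4L))
})

test_that("N codons translate to X and never terminate; bad input errors", {
  # ATG TNA TAA: the N codon reads as X instead of terminating early
  out <- find_circular_orfs(circ_tbl("ATGTNATAA"), min_aa = 1)
  frame0 <- out[out$start_offset == 0, ]
  expect_equal(frame0$protein, "MX")
  expect_equal(frame0$termination, "stop")
  expect_error(find_circular_orfs(circ_tbl("AT")), "length")
  expect_error(find_circular_orfs(circ_tbl("ATGUAA")), "ACGTN")
})

test_that("ORF selection policies behave as documented", {
  set.seed(8)
  d1 <- plant_circle_with_orf("rolling", 100L, 40L)
  d2 <- plant_circle_with_orf("single_pass", 150L, 30L)
  orfs <- find_circular_orfs(circ_tbl(c(d1$sequence, d2$sequence)), min_aa = 10)
  sel <- select_orfs(orfs, "longest_junction_spanning")
  expect_equal(nrow(sel), 1L)
  expect_true(all(sel$junction_spanning))
  expect_equal(nrow(select_orfs(orfs, "all")), 2L)
})
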