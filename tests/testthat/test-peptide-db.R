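test_that("trypsin digestion applies the K/R-not-before-P rule", {
  expect_setequal(digest("MKRAPK", max_missed = 0)$peptide,
                  c("MK", "R", "APK"))
  expect_equal(digest("AKPGR", max_missed = 0)$peptide, "AKPGR")
  expect_setequal(digest("MKR", max_missed = 1)$peptide,
                  c("MK", "R", "MKR"))
  expect_equal(nrow(digest("")), 0L)
})

test_that("zero-missed digestion reconstructs the protein and leaves no internal sites", {
  set.seed(17)
  for (i in 1:20) {
    prot <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                         sample(30:120, 1), replace = TRUE), collapse = "")
    peps <- digest(prot, max_missed = 0)
    expect_equal(paste(peps$peptide, collapse = ""), prot)
    expect_equal(peps$start_aa, c(0L, cumsum(head(peps$n_aa, -1))))
    # no internal K/R not followed by P
    internal_kr <- grepl("[KR](?!$)(?!P)", peps$peptide, perl = TRUE)
    expect_false(any(internal_kr))
  }
})

test_that("missed-cleavage counts are consistent with digestion sites", {
  peps <- digest("MKAKRPDKR", max_missed = 2)
  expect_true(all(peps$missed_cleavages <= 2))
  zero <- peps[peps$missed_cleavages == 0, ]
  one <- peps[peps$missed_cleavages == 1, ]
  # each 1-missed peptide is the concatenation of two adjacent 0-missed ones
  for (i in seq_len(nrow(one))) {
    parts <- zero[zero$start_aa >= one$start_aa[i] &
                    zero$start_aa + zero$n_aa <= one$start_aa[i] + one$n_aa[i], ]
    expect_equal(paste(parts$peptide, collapse = ""), one$peptide[i])
    expect_equal(nrow(parts), 2L)
  }
})

test_that("peptides from ORFs carry correct junction-span flags", {
  set.seed(21)
  design <- plant_circle_with_orf("rolling", 100L, 45L)
  orfs <- find_circular_orfs(
    tibble::tibble(circ_id = "c1", sequence = design$sequence), min_aa = 20)
  peps <- digest_peptides(orfs, max_missed = 0)
  # flags match the coordinate definition: codon span leaves [0, L) mod L
  L <- 100L
  nt_start <- orfs$start_offset[1] + 3L * peps$start_aa
  nt_end <- nt_start + 3L * peps$n_aa
  expected <- purrr::map2_lgl(nt_start, nt_end, function(s, e) {
    any(seq_len(4) * L > s & seq_len(4) * L < e)
  })
  expect_equal(peps$spans_junction, expected)
  expect_true(any(peps$spans_junction))  # a rolling ORF must cross
})

test_that("reference filtering removes substring matches, honours I/L rule and bounds", {
  peps <- tibble::tibble(
    peptide = c("AAAAAAAK", "CCCCCCCR", "IIIIIIIK", "SHORT"),
    circ_id = "c1", orf_id = "o1", start_aa = 0L,
    n_aa = nchar(peptide), missed_cleavages = 0L, spans_junction = TRUE
  )
  ref <- c(ref1 = "XXXAAAAAAAKYYY",      # exact internal substring
           ref2 = "ZZLLLLLLLKZZ")        # I/L-equivalent to IIIIIIIK
  out <- filter_unique_peptides(peps, ref, il_equivalence = TRUE, min_len = 7)
  expect_equal(out$peptide, "CCCCCCCR")  # SHORT fails the length floor
  expect_true(all(out$unique_vs_reference))

  out_noil <- filter_unique_peptides(peps, ref, il_equivalence = FALSE,
                                     min_len = 7)
  expect_setequal(out_noil$peptide, c("CCCCCCCR", "IIIIIIIK"))

  # empty reference: vacuous filter
  out_vac <- filter_unique_peptides(peps, character(), min_len = 7)
  expect_equal(nrow(out_vac), 3L)
})

test_that("survivors are verifiably absent from the reference by direct scan", {
  set.seed(23)
  design <- plant_circle_with_orf("single_pass", 180L, 50L)
  orfs <- find_circular_orfs(
    tibble::tibble(circ_id = "c1", sequence = design$sequence), min_aa = 20)
  peps <- digest_peptides(orfs)
  ref <- setNames(
    vapply(1:10, function(i) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                          300, replace = TRUE), collapse = ""), ""),
    paste0("r", 1:10))
  # make one peptide non-unique on purpose
  victim <- peps$peptide[which(peps$n_aa >= 7)[1]]
  ref[["r1"]] <- paste0(ref[["r1"]], victim)
  out <- filter_unique_peptides(peps, ref)
  expect_false(victim %in% out$peptide)
  for (p in out$peptide) {
    expect_false(any(grepl(collapse_il(p), collapse_il(ref), fixed = TRUE)))
  }
})

test_that("enlarging the reference never enlarges the surviving set", {
  set.seed(29)
  design <- plant_circle_with_orf("rolling", 130L, 55L)
  orfs <- find_circular_orfs(
    tibble::tibble(circ_id = "c1", sequence = design$sequence), min_aa = 20)
  peps <- digest_peptides(orfs)
  ref_small <- c(a = "MKKAAAAAAAR")
  ref_big <- c(ref_small, b = paste(peps$peptide[1:3], collapse = ""))
  s_small <- filter_unique_peptides(peps, ref_small)$peptide
  s_big <- filter_unique_peptides(peps, ref_big)$peptide
  expect_true(all(s_big %in% s_small))
  expect_lt(length(s_big), length(s_small))
})

test_that("the search database is deterministic, partitioned and collision-safe", {
  set.seed(19)
  design <- plant_circle_with_orf("single_pass", 120L, 30L)
  orfs <- find_circular_orfs(
    tibble::tibble(circ_id = "c1", sequence = design$sequence), min_aa = 20)
  ref <- c(sp1 = "MAAAAK", sp2 = "MCCCCR", sp3 = "MDDDDK")
  tf <- withr::local_tempfile(fileext = ".fa")
  write_search_database(orfs, ref, tf)
  db <- read_fasta(tf, type = "protein")
  expect_equal(length(db), 4L)
  expect_equal(names(db)[1:3], names(ref))          # reference first, unchanged
  expect_true(startsWith(names(db)[4], "CIRC|"))    # circRNA entries last
  tf2 <- withr::local_tempfile(fileext = ".fa")
  write_search_database(orfs, ref, tf2)
  expect_identical(readLines(tf), readLines(tf2))   # byte-identical rerun

  expect_error(write_search_database(orfs, c("CIRC|bad" = "MK"), tf),
               "reserved")
})
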