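test_that("planted circles always realise their designed ORF", {
  set.seed(83)
  for (i in 1:40) {
    kind <- sample(c("rolling", "single_pass", "infinite"), 1)
    if (kind == "rolling") {
      L <- sample((30:130)[(30:130) %% 3 != 0], 1)
      amin <- (L - 3L) %/% 3L + 1L
      targets <- max(10L, amin):(L - 1L)
      targets <- targets[vapply(targets, circpep:::stop_placement_feasible,
                                logical(1), L = L)]
      target <- targets[sample.int(length(targets), 1)]
    } else if (kind == "single_pass") {
      target <- sample(10:40, 1)
      L <- 3L * target + 3L + 3L * sample(2:10, 1)
    } else {
      target <- sample(10:40, 1)
      L <- 3L * target
    }
    d <- plant_circle_with_orf(kind, L, target)
    orfs <- find_circular_orfs(
      tibble::tibble(circ_id = "x", sequence = d$sequence), min_aa = 1)
    expect_equal(nrow(orfs), 1L)
    expect_equal(nchar(orfs$protein), target)
    expect_equal(orfs$start_offset, 0L)
    if (kind == "infinite") {
      expect_equal(orfs$termination, "none")
    } else {
      expect_equal(orfs$termination, "stop")
      expect_equal(orfs$junction_spanning, kind == "rolling")
    }
  }
})

test_that("infeasible circle designs are refused", {
  expect_error(plant_circle_with_orf("rolling", 99L, 40L), "divisible")
  expect_error(plant_circle_with_orf("rolling", 100L, 20L), "overrun")
  expect_error(plant_circle_with_orf("rolling", 100L, 120L), "infeasible")
  expect_error(plant_circle_with_orf("single_pass", 30L, 40L), "fit")
})

test_that("fixture generation is byte-identical under the same seed", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_circ_study(d1, seed = 7L, n_circles = 8L)
  simulate_circ_study(d2, seed = 7L, n_circles = 8L)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("the annotation and genome agree with the manifest", {
  d <- sim_fixture_dir()
  m <- sim_fixture_manifest()
  models <- read_gene_models(file.path(d, "genes.gtf"))
  expect_equal(dplyr::n_distinct(models$gene_id), m$parameters$n_circles)
  genome <- read_fasta(file.path(d, "genome.fa"))
  genes <- tibble::as_tibble(m$genes)
  # exon sequences re-extracted by coordinates match the planted pieces:
  # splicing them per gene model reproduces every circle sequence
  circles <- tibble::as_tibble(m$circles)
  seqs <- tibble::as_tibble(m$sequences)
  asm <- assemble_circ_sequence(
    circles[, c("circ_id", "chrom", "start", "end", "strand")],
    genome, models)
  expect_equal(asm$sequence, seqs$sequence[match(asm$circ_id, seqs$circ_id)])
})

test_that("caller files respect per-caller membership and the consensus truth", {
  d <- sim_fixture_dir()
  m <- sim_fixture_manifest()
  circles <- tibble::as_tibble(m$circles)
  calls <- dplyr::bind_rows(
    read_ciri2(file.path(d, "ciri2.tsv")),
    read_caller_bed(file.path(d, "ce2.bed"), "circexplorer2"),
    read_caller_bed(file.path(d, "findcirc.bed"), "find_circ")
  )
  cons <- build_consensus(calls, min_callers = 2)
  expect_setequal(cons$circ_id, m$truth$consensus_circ_ids)
  # a circle assigned to one caller only is excluded at min_callers = 2
  singles <- circles$circ_id[!grepl(",", circles$callers)]
  expect_false(any(singles %in% cons$circ_id))
})

test_that("noiseless PRM simulation returns the exact planted ratio", {
  set.seed(97)
  tr <- simulate_prm_transitions("AAAK", c("s1", "s2"), true_ratio = 1,
                                 cv = 0)
  expect_equal(compute_prm_ratios(tr)$ratio, c(1, 1))
  tr2 <- simulate_prm_transitions("AAAK", "s1", true_ratio = 0.25, cv = 0)
  expect_equal(compute_prm_ratios(tr2)$ratio, 0.25)
})
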