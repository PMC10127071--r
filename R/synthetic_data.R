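## Seeded synthetic-data generator. Stands in for real RNA-seq-derived
## caller outputs and proteomics tables: every fixture it writes has a machine-readable
## ground truth (the manifest), so each pipeline stage can be checked for
## exact recovery.

GENCODE <- Biostrings::GENETIC_CODE
STOP_CODONS <- names(GENCODE)[GENCODE == "*"]

#' Design a circle sequence with a single ORF of known structure
#'
#' Constructs a circular nucleotide sequence whose only ATG-initiated ORF has
#' exactly `target_aa` residues (or never terminates, for
#' `kind = "infinite"`). Three kinds are supported:
#' * `"single_pass"`: the ORF (including its stop) fits within one pass of
#'   the circle (`3*target_aa + 3 <= L`), so it never crosses the junction.
#' * `"rolling"`: `L` is not a multiple of 3 and `3*target_aa + 3 > L`, so
#'   translation reads through the back-splice junction and the frame shifts
#'   each pass — e.g. `circle_length = 322, target_aa = 161` reproduces the
#'   structure of a 322-nt circle encoding a 161-aa protein.
#' * `"infinite"`: `L = 3*target_aa` and frame 0 contains no stop, so the
#'   ORF is periodic.
#'
#' Construction places ATG at offset 0, the stop codon at coding offset
#' `3*target_aa` (positions taken modulo `L`), draws all remaining bases
#' from \{A,C,G\} (no T, so no spurious start or stop can assemble away from
#' the planted ones), and verifies the design by an independent scan of the
#' wrapped sequence, retrying with fresh random draws if a wrapped-frame
#' collision produced an early stop or extra ATG. Uses the session RNG: set
#' a seed for reproducibility.
#'
#' @param kind ORF structure to plant.
#' @param circle_length Circle length `L` in nt.
#' @param target_aa Designed protein length in residues (for `"infinite"`,
#'   the truncation length `L/3`).
#' @param max_tries Rejection-sampling retries before giving up.
#' @return A list with `sequence`, `kind`, `circle_length`, `target_aa`,
#'   `protein` (the designed translation product).
#' @export
plant_circle_with_orf <- function(kind = c("single_pass", "rolling",
                                           "infinite"),
                                  circle_length, target_aa,
                                  max_tries = 200L) {
  kind <- match.arg(kind)
  L <- as.integer(circle_length)
  target_aa <- as.integer(target_aa)
  if (L < 6L) stop("circle_length must be >= 6", call. = FALSE)
  if (kind == "single_pass" && 3L * target_aa + 3L > L) {
    stop("single_pass ORF does not fit: need 3*target_aa + 3 <= L",
         call. = FALSE)
  }
  if (kind == "rolling") {
    if (L %% 3L == 0L) {
      stop("rolling-circle translation requires L not divisible by 3",
           call. = FALSE)
    }
    if (3L * target_aa + 3L <= L) {
      stop("rolling ORF must overrun the circle: need 3*target_aa + 3 > L",
           call. = FALSE)
    }
    if (target_aa > L - 1L) {
      stop("infeasible: target_aa exceeds the L - 1 bound for a ",
           "stop-terminated ORF on a circle scanned over 3L nt",
           call. = FALSE)
    }
  }
  if (kind == "infinite" && L != 3L * target_aa) {
    stop("infinite kind requires circle_length == 3 * target_aa",
         call. = FALSE)
  }

  for (try in seq_len(max_tries)) {
    s <- rep(NA_character_, L)
    s[1:3] <- c("A", "T", "G")
    ok <- TRUE
    if (kind != "infinite") {
      stop_pos <- ((3L * target_aa + 0:2) %% L) + 1L
      placed <- FALSE
      for (stop_codon in c("TAA", "TAG", "TGA")) {
        letters3 <- strsplit(stop_codon, "")[[1]]
        clash <- !is.na(s[stop_pos]) & s[stop_pos] != letters3
        if (!any(clash)) {
          s[stop_pos] <- letters3
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("infeasible: planted stop codon collides with the start codon",
             call. = FALSE)
      }
    }
    free <- which(is.na(s))
    s[free] <- sample(c("A", "C", "G"), length(free), replace = TRUE)
    seq <- paste(s, collapse = "")
    if (planted_circle_ok(seq, kind, target_aa)) {
      return(list(sequence = seq, kind = kind, circle_length = L,
                  target_aa = target_aa,
                  protein = read_frame0_protein(seq, target_aa)))
    }
  }
  stop("could not design a valid circle in ", max_tries, " tries ",
       "(kind=", kind, ", L=", L, ", target_aa=", target_aa, ")",
       call. = FALSE)
}

# Independent design check: sole ATG at offset 0 (wrapped), reading frame 0
# yields exactly target_aa non-stop codons, then a stop (or no stop at all
# within P*L for kind = "infinite").
planted_circle_ok <- function(seq, kind, target_aa) {
  L <- nchar(seq)
  wrapped <- paste0(seq, substr(seq, 1, 2))
  codons_at <- substring(wrapped, 1:L, 3:(L + 2))
  if (!identical(which(codons_at == "ATG"), 1L)) return(FALSE)
  P <- if (L %% 3 == 0) 1L else 3L
  lin <- strrep(seq, P + 1L)
  pos <- 3L * (0:((P * L) %/% 3L - 1L)) + 1L
  codons <- substring(lin, pos, pos + 2L)
  stops <- which(codons %in% STOP_CODONS)
  if (kind == "infinite") return(length(stops) == 0)
  length(stops) > 0 && stops[1] == target_aa + 1L
}

read_frame0_protein <- function(seq, target_aa) {
  L <- nchar(seq)
  lin <- strrep(seq, 4L)
  pos <- 3L * (0:(target_aa - 1L)) + 1L
  paste(unname(GENCODE[substring(lin, pos, pos + 2L)]), collapse = "")
}

#' Simulate PRM transition areas with a known light/heavy ratio
#'
#' Heavy (spiked standard) areas are drawn uniformly on a realistic peak
#' scale; light (endogenous) areas are `heavy * true_ratio * noise` with
#' multiplicative lognormal noise of coefficient of variation `cv` — the
#' standard error model for chromatographic peak areas.
#'
#' @param peptides Character vector of peptide sequences.
#' @param samples Character vector of sample ids.
#' @param true_ratio True endogenous/heavy ratio.
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param n_transitions Transitions per precursor (>= 3).
#' @return A transition tibble in the [read_prm_table()] layout.
#' @export
simulate_prm_transitions <- function(peptides, samples, true_ratio = 0.5,
                                     cv = 0.1, n_transitions = 4L) {
  if (n_transitions < 3L) stop("n_transitions must be >= 3", call. = FALSE)
  sdlog <- sqrt(log(1 + cv^2))
  grid <- tidyr::expand_grid(peptide = peptides, sample = samples,
                             fragment = paste0("y", seq_len(n_transitions) + 3L))
  grid |>
    dplyr::mutate(
      heavy_area = runif(dplyr::n(), 1e5, 1e6),
      light_area = .data$heavy_area * true_ratio *
        exp(rnorm(dplyr::n(), mean = -sdlog^2 / 2, sd = sdlog))
    )
}

#' Generate a complete synthetic study with known ground truth
#'
#' Writes, under `out_dir`: `genome.fa`, `genes.gtf`, `ciri2.tsv` (1-based
#' inclusive, the tool's native dialect), `ce2.bed` and `findcirc.bed`
#' (0-based half-open), `proteome.fa`, `psms.tsv`, `prm.csv` and
#' `manifest.json`. Caller files are emitted in their native coordinate
#' dialects precisely to exercise the parsers' off-by-one handling.
#'
#' The manifest records every planted truth: gene/exon coordinates, circle
#' sequences and designed ORFs, per-caller detection, which circles received
#' true PSM support, planted reference-collision peptides, and the PRM true
#' ratio — so each stage's output can be compared against it exactly. The
#' expected end-to-end result is `manifest$truth$translatable_circ_ids`: the
#' circles detected by at least `min_callers` callers that were given
#' passing PSMs for circRNA-unique peptides.
#'
#' Defaults emulate the study conditions this pipeline targets: three
#' callers with imperfect, overlapping sensitivity; one flagship 322-nt
#' rolling-circle ORF of 161 aa among the planted circles; mostly
#' multi-exon, some minus-strand genes; PSM tables mixing circRNA-unique,
#' reference-only, shuffled-decoy and above-threshold rows; PRM at a known
#' ratio with 10% multiplicative noise.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; same seed, byte-identical fixtures.
#' @param n_circles Number of planted circles.
#' @param n_ref_proteins Reference proteome size.
#' @param caller_sensitivity Named per-caller detection probabilities.
#' @param min_callers Consensus rule used to define the expected truth set.
#' @param psm_fraction Fraction of eligible consensus circles given true PSM
#'   support.
#' @param true_ratio,cv,n_transitions PRM simulation parameters
#'   (see [simulate_prm_transitions()]).
#' @param prm_samples Sample ids for the PRM table.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
simulate_circ_study <- function(out_dir, seed = 1L, n_circles = 30L,
                                n_ref_proteins = 20L,
                                caller_sensitivity = c(ciri2 = 0.85,
                                                       circexplorer2 = 0.80,
                                                       find_circ = 0.75),
                                min_callers = 2L,
                                psm_fraction = 0.6,
                                true_ratio = 0.5, cv = 0.1,
                                n_transitions = 4L,
                                prm_samples = c("s1", "s2", "s3")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  callers <- names(caller_sensitivity)

  ## --- design circles -----------------------------------------------------
  designs <- vector("list", n_circles)
  for (i in seq_len(n_circles)) {
    if (i == 1L) {
      # flagship rolling circle: 322 nt, 161 aa across the junction
      designs[[i]] <- plant_circle_with_orf("rolling", 322L, 161L)
    } else {
      kind <- sample(c("rolling", "single_pass", "infinite"), 1,
                     prob = c(0.5, 0.35, 0.15))
      if (kind == "rolling") {
        cand <- 90:400
        L <- sample_one(cand[cand %% 3L != 0L])
        amin <- (L - 3L) %/% 3L + 1L          # force overrun of one pass
        targets <- max(25L, amin):(L - 1L)
        # drop the targets whose wrapped stop codon would straddle the fixed
        # start ATG in a way no stop codon can satisfy
        targets <- targets[vapply(targets, stop_placement_feasible,
                                  logical(1), L = L)]
        target <- sample_one(targets)
      } else if (kind == "single_pass") {
        target <- sample(25:80, 1)
        L <- 3L * target + 3L + 3L * sample(5:40, 1)
      } else {
        target <- sample(25:60, 1)
        L <- 3L * target
      }
      designs[[i]] <- plant_circle_with_orf(kind, L, target)
    }
  }

  ## --- place genes on a genome -------------------------------------------
  chrom_names <- c("chr1", "chr2")
  gene_rows <- list()
  circle_rows <- list()
  cursor <- setNames(rep(1L, length(chrom_names)), chrom_names)  # 1-based
  chrom_seq_parts <- setNames(vector("list", length(chrom_names)), chrom_names)
  for (i in seq_len(n_circles)) {
    d <- designs[[i]]
    chrom <- chrom_names[(i %% length(chrom_names)) + 1L]
    strand <- if (runif(1) < 0.3) "-" else "+"
    n_exons <- if (d$circle_length >= 60L) sample(2:3, 1) else 1L
    chunks <- split_sequence(d$sequence, n_exons)
    # genomic pieces: transcript order for +, reversed/revcomp'ed for -
    genomic_pieces <- if (strand == "+") chunks else rev(vapply(chunks, revcomp, ""))
    flank_up <- random_dna(sample(30:60, 1))
    flank_dn <- random_dna(sample(30:60, 1))
    pieces <- c(flank_up, genomic_pieces, flank_dn)
    intergenic <- random_dna(sample(100:300, 1))
    introns <- vapply(seq_len(length(pieces) - 1L),
                      function(k) random_dna(sample(50:150, 1)), "")
    pos <- cursor[[chrom]] + nchar(intergenic)   # 1-based start of first piece
    exon_coords <- matrix(0L, nrow = length(pieces), ncol = 2)
    p <- pos
    assembled <- intergenic
    for (k in seq_along(pieces)) {
      exon_coords[k, ] <- c(p - 1L, p - 1L + nchar(pieces[k]))  # 0-based half-open
      assembled <- paste0(assembled, pieces[k])
      p <- p + nchar(pieces[k])
      if (k < length(pieces)) {
        assembled <- paste0(assembled, introns[k])
        p <- p + nchar(introns[k])
      }
    }
    chrom_seq_parts[[chrom]] <- c(chrom_seq_parts[[chrom]], assembled)
    cursor[[chrom]] <- p
    gene_id <- sprintf("gene%02d", i)
    tx_id <- sprintf("tx%02d.1", i)
    gene_rows[[i]] <- tibble::tibble(
      gene_id = gene_id, transcript_id = tx_id, chrom = chrom,
      strand = strand, exon_start = exon_coords[, 1], exon_end = exon_coords[, 2]
    )
    circ_exons <- exon_coords[seq(2, length(pieces) - 1L), , drop = FALSE]
    start0 <- min(circ_exons[, 1]); end0 <- max(circ_exons[, 2])
    circle_rows[[i]] <- tibble::tibble(
      circ_id = circ_key(chrom, start0, end0, strand),
      gene_id = gene_id, chrom = chrom, start = start0, end = end0,
      strand = strand, circle_length = d$circle_length, kind = d$kind,
      target_aa = d$target_aa, n_exons = n_exons,
      sequence = d$sequence, protein = d$protein
    )
  }
  genome <- vapply(chrom_seq_parts, paste, "", collapse = "")
  # pad chromosome ends with background sequence
  genome <- vapply(genome, function(s) paste0(s, random_dna(200L)), "")
  names(genome) <- chrom_names
  models <- dplyr::bind_rows(gene_rows)
  circles <- dplyr::bind_rows(circle_rows)

  ## --- caller detection ---------------------------------------------------
  detection <- sapply(callers, function(cl) {
    runif(n_circles) < caller_sensitivity[[cl]]
  })
  # every circle detected somewhere; flagship seen by all callers
  detection[1, ] <- TRUE
  none <- rowSums(detection) == 0
  detection[none, 1] <- TRUE
  circles$callers <- lapply(seq_len(n_circles),
                            function(i) callers[detection[i, ]])
  circles$junction_reads <- as.integer(5L + rpois_int(n_circles, 20))
  consensus_ids <- circles$circ_id[rowSums(detection) >= min_callers]

  ## --- peptide ground truth ----------------------------------------------
  reference <- setNames(
    vapply(seq_len(n_ref_proteins), function(i) random_protein(sample(200:400, 1)), ""),
    sprintf("sp|REF%03d|SYN_REF%03d", seq_len(n_ref_proteins),
            seq_len(n_ref_proteins))
  )
  # plant reference collisions: one tryptic peptide of some circle ORFs is
  # embedded into a reference protein and must be filtered out downstream
  collision <- list()
  eligible <- which(circles$kind != "infinite" &
                      circles$circ_id %in% consensus_ids)
  for (i in head(eligible, 3)) {
    peps <- digest(circles$protein[i], max_missed = 0L)
    peps <- peps$peptide[nchar(peps$peptide) >= 7 & nchar(peps$peptide) <= 30]
    if (length(peps) == 0) next
    pep <- peps[1]
    j <- (i %% n_ref_proteins) + 1L
    reference[[j]] <- paste0(substr(reference[[j]], 1, 100), pep,
                             substring(reference[[j]], 101))
    collision[[length(collision) + 1L]] <-
      tibble::tibble(circ_id = circles$circ_id[i], peptide = pep,
                     reference_accession = names(reference)[j])
  }
  collision <- dplyr::bind_rows(collision)

  # candidate unique peptides per consensus circle (direct reference scan),
  # junction-spanning products first: they are the evidence class of interest
  hay <- collapse_il(paste(reference, collapse = "|"))
  unique_peps <- lapply(seq_len(n_circles), function(i) {
    if (circles$kind[i] == "infinite") return(character())
    peps <- digest(circles$protein[i], max_missed = 2L)
    peps <- peps[peps$n_aa >= 7 & peps$n_aa <= 30, ]
    L <- circles$circle_length[i]
    spans <- vapply(seq_len(nrow(peps)), function(k) {
      s <- 3L * peps$start_aa[k]; e <- s + 3L * peps$n_aa[k]
      any(seq_len(3) * L > s & seq_len(3) * L < e)
    }, logical(1))
    cand <- unique(peps$peptide[order(!spans)])
    cand[!vapply(collapse_il(cand), grepl, logical(1), x = hay, fixed = TRUE)]
  })

  ## --- PSM table ----------------------------------------------------------
  supportable <- which(circles$circ_id %in% consensus_ids &
                         lengths(unique_peps) > 0)
  n_true <- max(1L, round(psm_fraction * length(supportable)))
  true_idx <- sort(sample(supportable, n_true))
  psm_rows <- list()
  for (i in true_idx) {
    peps <- head(unique_peps[[i]], 2)
    for (pep in peps) {
      for (k in seq_len(sample(1:2, 1))) {
        psm_rows[[length(psm_rows) + 1L]] <- tibble::tibble(
          peptide = pep, accessions = "CIRC", q_value = runif(1, 0, 0.009),
          score = runif(1, 60, 140), truth = "circ_true",
          circ_id = circles$circ_id[i]
        )
      }
    }
  }
  # a non-consensus circle with a passing PSM: must NOT be recovered because
  # its ORF never enters the database
  off_consensus <- setdiff(which(lengths(unique_peps) > 0), supportable)
  if (length(off_consensus) > 0) {
    i <- off_consensus[1]
    psm_rows[[length(psm_rows) + 1L]] <- tibble::tibble(
      peptide = unique_peps[[i]][1], accessions = "CIRC",
      q_value = runif(1, 0, 0.009), score = runif(1, 60, 140),
      truth = "circ_not_in_consensus", circ_id = circles$circ_id[i]
    )
  }
  # an above-threshold PSM for a supportable circle not in the truth set
  sub_idx <- setdiff(supportable, true_idx)
  if (length(sub_idx) > 0) {
    i <- sub_idx[1]
    psm_rows[[length(psm_rows) + 1L]] <- tibble::tibble(
      peptide = unique_peps[[i]][1], accessions = "CIRC",
      q_value = runif(1, 0.05, 0.5), score = runif(1, 10, 40),
      truth = "circ_above_threshold", circ_id = circles$circ_id[i]
    )
  }
  # reference-only peptides: real tryptic products of reference proteins
  for (j in seq_len(min(5L, n_ref_proteins))) {
    peps <- digest(reference[[j]], max_missed = 0L)
    peps <- peps$peptide[nchar(peps$peptide) >= 7 & nchar(peps$peptide) <= 30]
    if (length(peps) == 0) next
    psm_rows[[length(psm_rows) + 1L]] <- tibble::tibble(
      peptide = peps[sample.int(length(peps), 1)],
      accessions = names(reference)[j], q_value = runif(1, 0, 0.009),
      score = runif(1, 60, 140), truth = "reference", circ_id = NA_character_
    )
  }
  # shuffled decoys absent from both databases
  all_seqs <- c(unname(reference), circles$protein)
  for (k in 1:5) {
    repeat {
      pep <- random_protein(sample(8:15, 1))
      if (!any(vapply(all_seqs, grepl, logical(1), pattern = pep,
                      fixed = TRUE))) break
    }
    psm_rows[[length(psm_rows) + 1L]] <- tibble::tibble(
      peptide = pep, accessions = "DECOY", q_value = runif(1, 0, 0.009),
      score = runif(1, 20, 60), truth = "decoy", circ_id = NA_character_
    )
  }
  psms <- dplyr::bind_rows(psm_rows)

  ## --- PRM table ----------------------------------------------------------
  prm_peptides <- unlist(lapply(true_idx, function(i) head(unique_peps[[i]], 1)))
  prm <- simulate_prm_transitions(prm_peptides, prm_samples,
                                  true_ratio = true_ratio, cv = cv,
                                  n_transitions = n_transitions)

  ## --- write fixtures -----------------------------------------------------
  write_fasta(genome, file.path(out_dir, "genome.fa"), type = "dna")
  write_gtf(models, file.path(out_dir, "genes.gtf"))
  write_caller_fixtures(circles, detection, callers, out_dir)
  write_fasta(reference, file.path(out_dir, "proteome.fa"), type = "protein")
  readr::write_tsv(psms[, c("peptide", "accessions", "q_value", "score")],
                   file.path(out_dir, "psms.tsv"), progress = FALSE)
  readr::write_csv(prm, file.path(out_dir, "prm.csv"), progress = FALSE)

  manifest <- list(
    seed = seed,
    parameters = list(
      n_circles = n_circles, n_ref_proteins = n_ref_proteins,
      caller_sensitivity = as.list(caller_sensitivity),
      min_callers = min_callers, psm_fraction = psm_fraction,
      true_ratio = true_ratio, cv = cv, n_transitions = n_transitions,
      prm_samples = prm_samples
    ),
    genome = list(chroms = as.list(setNames(nchar(genome), names(genome)))),
    genes = as.data.frame(models),
    circles = as.data.frame(dplyr::select(
      dplyr::mutate(circles,
                    callers = vapply(.data$callers, paste, "", collapse = ",")),
      -"sequence", -"protein")),
    sequences = as.data.frame(circles[, c("circ_id", "sequence", "protein")]),
    reference_collisions = as.data.frame(collision),
    psm_truth = as.data.frame(psms),
    truth = list(
      consensus_circ_ids = consensus_ids,
      translatable_circ_ids = circles$circ_id[true_idx],
      prm_peptides = prm_peptides
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(manifest)
}

## -- internal helpers ------------------------------------------------------

sample_one <- function(x) x[sample.int(length(x), 1L)]

# TRUE when some stop codon is compatible with the fixed start-ATG letters
# at the (mod L) positions the stop would occupy
stop_placement_feasible <- function(target_aa, L) {
  pos <- (3L * target_aa + 0:2) %% L
  fixed <- ifelse(pos <= 2L, c("A", "T", "G")[pos + 1L], NA_character_)
  any(vapply(c("TAA", "TAG", "TGA"), function(sc) {
    letters3 <- strsplit(sc, "")[[1]]
    all(is.na(fixed) | fixed == letters3)
  }, logical(1)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

rpois_int <- function(n, lambda) as.integer(stats::rpois(n, lambda))

# split a sequence into n contiguous chunks, each at least 15 nt
split_sequence <- function(seq, n) {
  L <- nchar(seq)
  if (n == 1L) return(seq)
  repeat {
    cuts <- sort(sample(seq_len(L - 1L), n - 1L))
    sizes <- diff(c(0L, cuts, L))
    if (all(sizes >= 15L)) break
  }
  substring(seq, c(1L, cuts + 1L), c(cuts, L))
}

# native-dialect caller files: CIRI2 1-based inclusive TSV, the BED dialects
# 0-based half-open
write_caller_fixtures <- function(circles, detection, callers, out_dir) {
  for (cl in callers) {
    idx <- which(detection[, cl])
    sub <- circles[idx, , drop = FALSE]
    if (cl == "ciri2") {
      lines <- c(
        paste("circRNA_ID", "chr", "circRNA_start", "circRNA_end",
              "#junction_reads", "SM_MS_SMS", "circRNA_type", "strand",
              sep = "\t"),
        sprintf("%s\t%s\t%d\t%d\t%d\t%d_%d_%d\texon\t%s",
                sub$circ_id, sub$chrom, sub$start + 1L, sub$end,
                sub$junction_reads, sub$junction_reads, 0L, 0L, sub$strand)
      )
      writeLines(lines, file.path(out_dir, "ciri2.tsv"))
    } else {
      fname <- if (cl == "circexplorer2") "ce2.bed" else "findcirc.bed"
      lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                       sub$chrom, sub$start, sub$end, sub$circ_id,
                       sub$junction_reads, sub$strand)
      writeLines(lines, file.path(out_dir, fname))
    }
  }
  invisible(NULL)
}
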