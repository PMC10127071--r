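# circpep

Discovery and quantification of protein-coding circular RNAs (circRNAs)
from caller outputs and mass-spectrometry evidence.

Back-splicing joins a downstream splice donor to an upstream acceptor and
produces a covalently closed RNA circle. Some circles are translated, but
their proteins are invisible to standard proteomics because search
databases contain only linear gene models. `circpep` is the bioinformatic
side of a translatable-circRNA screen, for RNA biologists and
proteogenomics analysts who already have caller outputs and search-engine
results in hand:

* **Consensus back-splice junctions** — parses CIRI2 (1-based inclusive),
  CIRCexplorer2 and find_circ (BED-style, 0-based half-open) outputs,
  normalizes everything to 0-based half-open coordinates, and keeps circles
  called by at least *k* of *n* tools (default 2 of 3).
* **Circle assembly** — splices annotated exons inside the junction span
  and reverse-complements minus-strand circles.
* **Circular ORF prediction** — translation is defined on the infinite
  repetition of the circle. The reading frame at a start offset recurs
  after *P* passes (*P* = 1 if 3 | *L*, else 3), so scanning *P·L* nt
  decides every ORF. When *L* is not a multiple of 3, an ORF can read
  through the junction repeatedly (**rolling-circle translation**): a
  322-nt circle can encode a 161-aa protein, since 3×161+3 = 486 > 322.
* **circRNA-unique peptide database** — in-silico tryptic digestion
  (K/R, not before P, ≤2 missed cleavages), removal of every peptide that
  occurs as a substring of any reference protein (I/L collapsed, since
  they are isobaric in MS), and a combined search FASTA whose circRNA
  entries carry a `CIRC|` accession prefix.
* **PSM evidence** — PSMs at q ≤ 0.01 matching circRNA-unique peptides
  nominate translatable circles; every nomination is flagged for human
  review with a per-PSM detail table.
* **PRM quantification** — endogenous/heavy ratio as the ratio of summed
  transition peak areas (≥3 transitions per precursor enforced), with
  Welch two-tailed unpaired t-tests between sample groups.
* **Synthetic studies** — a seeded generator plants circles with known ORF
  structure (single-pass / rolling / non-terminating), caller files in
  native dialects, a reference proteome with deliberate collisions, PSM and
  PRM tables — so every stage can be tested against exact ground truth.

## Worked example

Simulate a small study and run the whole pipeline:

```r
library(circpep)

simulate_circ_study("simdir", seed = 7, n_circles = 12)

run <- run_all(circpep_config(
  ciri2          = "simdir/ciri2.tsv",
  circexplorer2  = "simdir/ce2.bed",
  find_circ      = "simdir/findcirc.bed",
  genome_fasta   = "simdir/genome.fa",
  annotation_gtf = "simdir/genes.gtf",
  proteome_fasta = "simdir/proteome.fa",
  psm_table      = "simdir/psms.tsv",
  prm_table      = "simdir/prm.csv",
  out_dir        = "outdir"
))
print(run)
#> circpep pipeline run
#> outputs in: outdir
#>
#> # A tibble: 6 × 3
#>   stage      n_in n_out
#>   <chr>     <int> <int>
#> 1 consensus    28    11
#> 2 sequence     11    11
#> 3 orfs         11    11
#> 4 digest-db   681   350
#> 5 evidence     28     5
#> 6 prm          60    15
#>
#> translatable circRNAs nominated: 5 (all flagged for review)
```

The funnel reads: 28 caller calls collapse to 11 consensus circles (≥2 of
3 callers); all 11 assemble and carry an ORF of ≥20 aa; digestion yields
681 candidate peptides of which 350 survive the reference-proteome filter;
28 PSMs nominate 5 circles; 15 precursor × sample PRM ratios are computed.

```r
dplyr::select(run$evidence, circ_id, n_unique_peptides, n_spectra,
              n_junction_spanning)
#> # A tibble: 5 × 4
#>   circ_id           n_unique_peptides n_spectra n_junction_spanning
#>   <chr>                         <int>     <int>               <int>
#> 1 chr1:367-717(-)                   2         4                   0
#> 2 chr1:1167-1651(+)                 2         3                   2
#> 3 chr1:2223-2535(-)                 2         3                   2
#> 4 chr1:2984-3164(+)                 2         3                   2
#> 5 chr2:343-945(+)                   2         3                   2

head(run$prm_ratios[, c("peptide", "sample", "n_transitions", "ratio")], 4)
#> # A tibble: 4 × 4
#>   peptide                sample n_transitions ratio
#>   <chr>                  <chr>          <int> <dbl>
#> 1 ARAREWR                s1                 4 0.545
#> 2 ARAREWR                s2                 4 0.490
#> 3 ARAREWR                s3                 4 0.505
#> 4 ARHPEERTSGETQDAPWTNEAR s1                 4 0.500
```

`n_junction_spanning` counts supporting peptides whose codon span crosses
the back-splice junction — the peptides that cannot derive from the linear
host mRNA. The PRM ratios scatter around the planted light/heavy ratio of
0.5. `autoplot()` methods exist for the consensus, ORF and PRM tables, and
`tidy()`/`glance()` summarize runs and group comparisons.

Individual stages are ordinary tibble-in/tibble-out functions and chain
with the pipe, e.g.

```r
find_circular_orfs(circles, min_aa = 20) |>
  digest_peptides(max_missed = 2) |>
  filter_unique_peptides(read_fasta("proteome.fa", type = "protein"))
```

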