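# piratlas

Small-RNA sequencing analysis for the *Drosophila* ovary piRNA pathway:
biotype classification, de novo piRNA cluster discovery, ping-pong
signature scanning, 1U-bias matrices, and transposable-element / 3'UTR
piRNA quantification — built tidyverse-style (tibbles in, tibbles out)
on top of Bioconductor's GenomicRanges/Rsamtools/Biostrings machinery.

## The problem

Germline stem cells (GSCs) and their early progeny silence transposable
elements (TEs) through PIWI-interacting RNAs (piRNAs): 23–30 nt small
RNAs with a strong uridine bias at the first position (1U), produced from
genomic piRNA clusters and amplified through the Aub/Ago3 "ping-pong"
cycle, whose hallmark is sense/antisense read pairs with 5′ ends
overlapping by exactly 10 nt. Quantifying this system from small-RNA
sequencing takes a chain of specialised steps that are easy to get subtly
wrong: length windows per biotype, strictly defined cluster thresholds,
multi-mapper handling, and normalization schemes (miRNA counts or
synthetic spike-ins) that deliberately preserve global piRNA shifts.
`piratlas` implements that chain as tested, composable functions for
anyone analysing gonadal small-RNA libraries or benchmarking cluster
callers against synthetic ground truth.

## What it implements

* **Biotype classification** — fixed precedence per read:
  structural RNA overlap (rRNA/tRNA/snoRNA/snRNA) excludes; ≤ 24 nt over
  a pre-miRNA → miRNA; ≤ 22 nt over an endo-siRNA locus or exactly 21 nt
  on a transposon → siRNA; remaining 23–30 nt reads → piRNA.
* **Cluster discovery** — a sliding-window density scan on deduplicated
  23–35 nt reads: merge read regions within 250 nt; drop regions under
  3 unique reads/kb; merge survivors within 1,000 nt; keep clusters
  strictly larger than 2,000 nt. Canonical cluster fragments separated by
  less than 25 kb are collapsed, keeping the largest.
* **Ping-pong signatures** — the 5′-overlap histogram over distances
  1–30, a per-cluster count of distinct overlap-10 position pairs, and an
  enrichment z-score
  `z10 = (c10 − mean(c_d, d≠10)) / sd(c_d, d≠10)`.
* **1U bias** — per-position base frequencies over the first 10 nt of
  unique piRNA 5′ sites, extracted from the genome in read orientation.
* **Quantification & normalization** — feature counting (≥ 1 bp overlap,
  sense/antisense aware), CPM/RPKM, miRNA-count denominators (excluding
  the two most differential miRNAs), spike-in factors with effective
  library sizes, CPM expression filters, an exact-binomial two-group
  stand-in test, Benjamini–Hochberg FDR, and |FC| ≥ 2 & FDR ≤ 0.05 calls.
* **Synthetic data** — a deterministic generator of toy genomes,
  annotations, and libraries with planted clusters (uni-/dual-strand),
  ping-pong pairs at exact distance 10, 1U bias written into the genome,
  miRNA/siRNA/structural reads, TE-consensus reads and spike-ins — with
  full ground truth for recovery testing.

## Worked example

```r
library(piratlas)
library(dplyr)

# simulate a six-sample GSC-vs-SC study with known ground truth
study <- generate_study(default_study_config(seed = 1), "study")

# reads back from the SAM files the generator wrote
ann   <- read_annotations("study/annotations.gff3")
reads <- bind_rows(lapply(c("GSC1", "SC1"), function(s)
  read_alignments(file.path("study", paste0(s, ".genome.sam")), "genome") |>
    mutate(sample_id = s)))

classify_library(reads, ann)
#> # A tibble: 10 × 3
#>    sample_id biotype                 n
#>    <chr>     <fct>               <int>
#>  1 GSC1      structural_excluded   800
#>  2 GSC1      miRNA                3000
#>  3 GSC1      siRNA                 800
#>  4 GSC1      piRNA               10054
#>  5 GSC1      other                   0
#>  6 SC1       structural_excluded   800
#>  7 SC1       miRNA                3000
#>  8 SC1       siRNA                 800
#>  9 SC1       piRNA                2783
#> 10 SC1       other                   0

pir <- select_putative_pirnas(reads, ann, purpose = "discovery")
discover_clusters(pir) |> select(chrom, start, end, n_unique_reads, density)
#> # A tibble: 10 × 5
#>   chrom      start    end n_unique_reads density
#>   <chr>      <int>  <int>          <int>   <dbl>
#> 1 chr2L_syn  20005  31988           2381   199.
#> 2 chr2L_syn  60017  64999            594   119.
#> 3 chr2L_syn 100010 108010           1020   128.
#> 4 chr2L_syn 150018 169996           1404    70.3
#> # ℹ 6 more rows

gsc <- filter(reads, sample_id == "GSC1")
prof <- ping_pong_histogram(select_putative_pirnas(gsc, ann))
prof
#> ping-pong profile: 9327 pairs over 10054 reads; z10 = 105.75 (multiplicity-weighted)
autoplot(prof)          # histogram with the d = 10 bin highlighted
```

The 10 discovered clusters match the 10 planted ones; the
ping-pong-active GSC sample scores z10 around 100 against near-zero for
SC samples; a GSC library carries roughly 3.6x the piRNA reads of an SC
library. Exact numbers vary with the seed.

The pipeline can also be driven end to end from a YAML config, in R
(`run_all("run.yaml")`) or from the shell:

```sh
Rscript inst/cli/piratlas.R simulate --seed 1 --out study
Rscript inst/cli/piratlas.R all --config run.yaml
```

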