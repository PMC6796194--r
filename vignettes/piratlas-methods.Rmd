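---
title: "piratlas: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{piratlas: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes, why the
defaults are what they are, and where genuinely open design choices were
made. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## Coordinates and core conventions

Every interval in the package is 0-based half-open (BED-compatible);
GFF3 input is shifted by (−1, 0) on ingest and never stored in 1-based
form. A single convention end to end removes the usual off-by-one drift
between BED, GFF3 and SAM-derived coordinates. Overlap means "at least
one shared base"; no fraction-of-read thresholds are used anywhere.
Only primary alignments are ingested from SAM/BAM; multi-mapper status
travels as the `NH` tag (`n_hits`), and alignments of 15 nt or shorter
are dropped at ingest — the small-RNA range this package models starts
above 15 nt. Spike-in counts are supplied as a separate TSV rather than
inferred from alignments, because spike references are not part of the
genome.

## Biotype classification

Reads are classified by length windows and annotation overlap, in fixed
precedence:

1. any overlap with rRNA, tRNA, snoRNA or snRNA excludes the read
   (`structural_excluded`);
2. reads of ≤ 24 nt over an annotated pre-miRNA are miRNAs;
3. reads of ≤ 22 nt over an endo-siRNA locus, or exactly 21 nt on a
   transposon (TE-consensus alignment or a genomic TE insertion), are
   siRNAs;
4. remaining reads of 23–30 nt are piRNAs;
5. everything else is `other`.

The precedence order follows the narrative order in which the rules are
usually stated; no authoritative tie-break exists for reads overlapping
several categories (e.g. a 21-nt read over both a pre-miRNA and a TE),
so the order above is a documented decision, not inferred intent.
Overlap tests at this layer are strand-blind; strand only matters in
quantification and signature scanning. The whole rule table is verified
against an independently written nested-conditional oracle over all
lengths 16–35 × all 2⁷ annotation-flag combinations (2,560 cases).

Two read universes feed downstream stages. Feature *counting* uses
uniquely-mapping (`n_hits == 1`) reads classified piRNA, 23–30 nt.
Cluster *discovery* uses a wider 23–35 nt window, keeps multi-mappers,
and excludes only reads claimed by the structural/miRNA/siRNA rules —
the discovery step names its own window, so it is drawn before the
23–30 piRNA label is applied.

## Cluster discovery

The scan works per contig on reads deduplicated by
(chrom, start, end, strand) — that is the "unique read" universe whose
count defines density:

1. seed regions are the union of read footprints;
2. regions within 250 nt of one another are merged (inclusive: a gap of
   exactly 250 merges);
3. regions with fewer than 3 unique reads per kb are discarded;
4. survivors within 1,000 nt are merged (inclusive);
5. only regions **strictly** longer than 2,000 nt are kept.

Three numerical choices deserve a note:

* **Seeding.** The window length and step of the original sliding-window
  formulation are unspecified; seeding by the union of read footprints
  is the parameter-free limit of a 1-nt-step window, and any window
  shorter than the 250-nt merge gap produces the same result after
  step 2.
* **Inclusive vs strict.** "Within 250 nt" and "within 1,000 nt" are read
  as inclusive merges; "greater than 2,000 nt" is strict (a final region
  of exactly 2,000 nt is never reported), and the canonical-fragment
  rule "less than 25 kb" is strict the other way.
* **Density filter reach.** With footprint-union seeding, a step-2
  region built from ≤ 35-nt reads with gaps ≤ 250 nt always has density
  of at least ≈ 3.5 unique reads/kb, so the 3/kb filter can only remove
  regions in degenerate or wide-footprint inputs. It is nonetheless
  implemented and tested literally — the filter's reach depends on the
  seeding choice, and users can lower `seed_merge_gap` or raise
  `min_density` to make it bite.

A consequence of step 4 worth knowing: isolated reads form tiny,
high-density regions (one 26-nt read alone is ≈ 38 reads/kb), so a chain
of single reads spaced under 1,000 nt can merge into a sparse region
longer than 2,000 nt and be reported. This is a genuine output of the
literal five-step procedure — the brute-force oracle in the test suite
produces the same calls — and is why diffuse background at rates around
0.5 reads/kb can yield occasional calls. Density and counts reported in
a `ClusterCall` row are always recomputed over the final extent.

Canonical cluster harmonization collapses overlapping fragments per
cluster name, merges fragments separated by less than 25 kb, and keeps
only the largest remaining fragment (ties broken by the smaller start).

Cluster strand composition is a derived statistic: ≥ 90% plus-strand
reads is `uni_plus`, ≤ 10% is `uni_minus`, anything between is `dual`;
discovered cluster intervals themselves are unstranded.

## Ping-pong signatures

For a plus-strand read with 5′ end at p and a minus-strand read with 5′
end at q (its rightmost aligned base), the 5′-overlap distance is
d = q − p + 1; the ping-pong amplification loop cleaves at the 10th
nucleotide, so genuine pairs sit at d = 10. Two counting modes are
exposed because the field's "number of ping-pong signatures" is used
both ways: multiplicity-weighted pair counts (default for histograms)
and distinct 5′-position pairs (used for the per-cluster signature
count). The enrichment score

z10 = (c₁₀ − mean(c_d, d ≠ 10)) / sd(c_d, d ≠ 10)

uses the sample standard deviation over distances 1–30 excluding 10.
It is this package's own statistic — external ping-pong tools define
their own — and is labelled `z10` in all outputs. A perfectly flat
histogram scores 0; any other zero-sd background leaves the score
undefined (`NA`), which is a value, not an error. No FDR is attached to
z10.

## 1U bias

Reads are collapsed to unique (chrom, 5′ position, strand) sites; the
10-nt genomic sequence starting at each 5′ site is extracted in read
orientation (reverse-complemented for minus-strand sites), and
per-position base fractions are tallied with T reported as U. Only the
matrix is produced — rendering a graphical logo is left to plotting
packages; `autoplot()` gives a stacked-fraction view.

## Quantification and normalization

Counting is multi-assignment: a read increments every feature it
overlaps by ≥ 1 bp, with no fractional weights — overlapping features
each see the read. CPM is count/denominator × 10⁶ where the denominator
is an explicit argument: total mapped reads, miRNA-count denominators,
or spike-in effective library sizes.

**miRNA denominators** sum each sample's miRNA counts after dropping the
two most differentially expressed miRNAs. "Most differential" is
operationalised as the largest |log2 ratio of group-mean raw counts|
(pseudo-count 1): ranking on CPM normalized by a miRNA total that
contains the candidate itself inverts the ranking — a strongly spiked
miRNA inflates its sample's total and so looks *less* differential than
everything else — so raw group means are the right basis. With fewer
than two condition groups the ranking falls back to cross-sample
log-count variance, with a warning.

**Spike-in factors** are proportional to 1/spike-total, rescaled to
geometric mean 1; the effective library size is total mapped reads ×
factor. This construction preserves genuine global piRNA shifts — the
point of spike-ins — while removing depth differences.

The expression filter keeps features with CPM strictly above the cutoff
in at least `min_samples` samples (defaults 20 and 3; the published
small-RNA cutoffs were 20 for clusters, 700 for antisense 3′UTRs, 1,000
for sense 3′UTRs, and 10 for mRNA — the cutoff is a parameter because it
is feature-class specific). Significance calling is |FC| ≥ 2 and
BH-FDR ≤ 0.05, both inclusive. The inferential test is an explicitly
labelled stand-in (`binomial_standin`): a two-sided exact binomial test
of the pooled group-A count against the proportion implied by the summed
denominators. It is *not* a negative-binomial GLM and makes no attempt
at dispersion estimation; it exists so the fold-change/FDR calling
machinery is exercised end to end with a defensible p-value, and can be
swapped for an external DGE engine by supplying per-feature p-values
directly to `benjamini_hochberg()` and `call_significant()`.

3′UTR producer classes are assigned per gene from piRNA reads over the
gene's 3′UTR: sense (gene-strand) and antisense counts each compared to
`min_count`, default 1 — the threshold behind published producer-gene
tallies is unstated, so it is exposed as a parameter. `has_te_fragment`
flags 3′UTRs overlapping an annotated TE insertion.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes:

* piRNA lengths from a fixed distribution peaked over 24–27 nt
  ({23: 0.10, 24: 0.17, 25: 0.22, 26: 0.22, 27: 0.17, 28: 0.07,
  29: 0.03, 30: 0.02}) — a symmetric peak consistent with ovarian
  libraries; the exact shape is a fixture choice, not a claim;
* planted clusters with Poisson read counts
  (reads/kb × length × per-sample scale), uni- or dual-strand;
* ping-pong pairing: a configurable fraction of cluster reads receive an
  opposite-strand partner at exact 5′-overlap 10, switchable per sample
  (`pingpong`), so GSC-like (on) vs SC-like (off) contrasts can be
  simulated;
* a first-position U probability of 0.8, realised by editing the genome
  base at each chosen 5′ site before sequence extraction, so the
  frequency matrix recovers the bias *from the FASTA* and reads stay
  consistent with the genome. The U/non-U decision is drawn once per
  genome position (first decision wins); a site on the opposite strand
  of an already-decided position reads through the existing base, so in
  dense dual-strand clusters the realised site-level U fraction sits
  slightly below 0.8, while sparse or uni-strand configurations recover
  it exactly;
* miRNA reads peaked at 22 nt on pre-miRNA loci, exactly-21-nt siRNAs on
  endo-siRNA loci, 23–30 nt structural contamination on rRNA/tRNA loci,
  3′UTR piRNAs on gene models, TE-consensus-space reads, and per-sample
  spike-in totals;
* gene models (with the last 400 nt as 3′UTR) and a per-sample
  `pingpong` switch are generator extensions beyond the minimal recipe —
  the 3′UTR analysis needs genes, and the condition contrast needs
  per-sample control of pairing.

Outputs are SAM (plus a BED6 mirror), FASTA, GFF3/BED, a spike TSV and a
JSON truth/manifest; identical config + seed gives byte-identical files.
Read counts are Poisson rather than fixed so threshold behaviour is
exercised stochastically; recovery tests use densities of ≥ 5 reads/kb,
where recovery is deterministic in practice.

The default study (`default_study_config()`) is six samples — three
GSC-like (3× piRNA content, ping-pong on) and three SC-like — over a
1.1-Mb two-contig genome with ten planted clusters (3–25 kb, 10–40
unique reads/kb, mixed strandedness), roughly 90,000 reads in total.
Its unclustered background is zero: with six samples pooled, even a
modest per-sample background reaches pooled inter-read gaps below the
1,000-nt merge threshold, and the literal algorithm then correctly
reports sparse chains — which is interesting behaviour for a benchmark
but wrong for a fixture whose purpose is an exact one-to-one match
between discovered and planted clusters. Background behaviour is
exercised separately through `background_reads_per_kb`, including the
0.5 reads/kb setting used in the acceptance checks, where any emitted
call must be certified by the brute-force oracle.

### What passing tests do and do not show

The generator reproduces the *coordinate and count structure* of
ovarian small-RNA libraries, not their sequence biology: there is no
adapter or sequencing-error simulation, no secondary structure, no
Piwi/Aub/Ago3 loading asymmetry, no 10A bias, and TE insertions are
single mutated copies rather than nested repeat landscapes. Recovery of
planted truth therefore validates the bookkeeping — windows, thresholds,
strand logic, normalization arithmetic — not the biological fidelity of
any particular dataset.

## Problem sizes in the tests

The test suite and acceptance script choose sizes that make the checked
properties sharp: 50 random 200-read sets for oracle equivalence; a 2-Mb
genome with 20 planted clusters (2.5–30 kb, 5–50 reads/kb) for
recall/precision; 20 seeded ~780-read libraries per ping-pong condition;
~12,000-read libraries for the 2-fold spike-in recovery (so per-seed
Poisson noise sits well inside the 5% band); ~11,000 unique uni-strand
sites for the 1U check (binomial ±0.012 at 3σ against the ±0.02 band);
and the default six-sample study for the end-to-end run. These sizes are
the package's own choices, stated here so the tolerances can be read
against them.

## Known limitations

* The density filter is near-vacuous under default seeding (see above).
* The stand-in test ignores biological replicate dispersion; its
  p-values are anti-conservative for overdispersed counts and are meant
  for pipeline plumbing, not publication-grade inference.
* Cluster discovery treats all multi-mappers as ordinary reads
  (deduplicated by coordinates); no fractional allocation is attempted.
* liftOver between assemblies, alignment itself, and exon-usage or GO
  analyses are out of scope.
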