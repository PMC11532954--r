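---
title: "g4scape methods: pG4 scanning, feature enrichment and expression variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{g4scape methods: pG4 scanning, feature enrichment and expression variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4scape)
```

## The problem

Putative G-quadruplex sequences (pG4) — at least four runs of three or
more guanines separated by short loops — cover roughly a third of a
percent of the human genome and concentrate at promoters, splice sites
and UTRs, where they correlate with transcription levels, transcriptome
variability, and mutation load. `g4scape` implements the full analysis
chain around that observation: scan genomes for the motif, intersect
hits with gene-regulatory features, EST transcription start sites and
mutation catalogs, and compute the associated enrichment, expression and
folding-context statistics. Because the real inputs (whole genome
assemblies, EST libraries, tumor expression cohorts, curated mutation
catalogs) are far beyond desk scale, the package ships a seeded
synthetic-data generator that plants ground truth for every downstream
stage, so each statistic can be validated in a closed loop.

## The motif and the scanner

The canonical motif is $G_{r}(N_{1-7}G_{r})_{\ge 3}$ with $r = 3$: four
or more maximal runs of at least `min_run_length` guanines, consecutive
runs separated by loops of `loop_min` to `loop_max` bases. All four
dimensions are exposed through `scan_params()`. Loops longer than 7 bp
are excluded by default because the corresponding structures are
predicted to be unstable; descriptions of G4 biology sometimes allow
loops up to about 22 bases, so the bound is a parameter rather than a
constant.

The scanner (`scan_strand()`) finds maximal G runs and chains them
greedily: a chain extends while the gap to the next run is a legal loop
(length in bounds, no `N`, only A/C/G/T); a chain of at least
`min_runs` runs is one hit, and scanning resumes after its end. The
conventions that matter:

* **Leftmost-greedy, non-overlapping per strand.** The first chainable
  run starts the match, extension is maximal, and matches never overlap
  on one strand (quadparser-family behaviour).
* **A long G run is one run.** A run of, say, 15 guanines is consumed
  whole; it is never split into run + one-guanine loop + run. The
  equivalent PCRE (`pg4_regex()`) therefore uses possessive quantifiers.
* **`N` breaks motifs.** Neither runs nor loops may contain `N`, so a
  motif never spans an assembly gap, which keeps covered-base accounting
  consistent with ungapped genome lengths.
* **Soft-masked lowercase is treated as sequence** by default
  (`mask_lower = TRUE` converts it to `N` instead).
* **Coordinates are 0-based half-open** (BED convention) everywhere.

`scan_genome()` scans the plus strand and the reverse complement,
mapping minus-strand hits back to the forward axis. When a single
genomic "pG4 bp" figure is needed, `merged_pg4_bp()` takes the union of
both strands' intervals; whether historical per-assembly counts merged
strands is not documented anywhere we know of, so the union is an
explicit, stated choice, and per-strand hits remain available.

The scanner is validated two ways: against an independent regex route
(`scan_strand_regex()`, same semantics expressed through the PCRE
engine) on a thousand seeded random sequences, and against planted
motifs in synthetic genomes, which must be recovered at exact
coordinates.

## Features and profiles

`derive_features()` computes, per gene (union over transcripts sharing a
`gene_id`): TSS, the single position 45 bp upstream of the TSS in
transcript orientation (`tss_upstream` is a parameter; the feature is a
point, not a 45-bp window — "45 bp before a TSS" names a position),
UTRs from CDS bounds, exons, introns, and splice-site points. For an
intron $[a, b)$ on the plus strand the 5' (donor) site is the base at
$a$ and the 3' (acceptor) site the base at $b$; minus-strand genes
mirror this so the site is always the first base downstream of the
junction in transcript orientation.

For all feature-overlap questions (`partition_genes()`,
`est_tss_overlap()`, `splice_profile()`) pG4 strand is ignored: a motif
on either strand marks the locus. EST start sites use half-open
containment, so a start coinciding with the base just past a motif does
not count.

`splice_profile()` counts, for every splice site, each pG4-covered base
within ±`window` (default 2500 bp) at its signed transcript-orientation
offset; counting is per covered base, not per motif, and junction bases
sit at offset 0. `profile_enrichment()` divides each offset's count by
the side's mean count; ties in the argmax resolve to the most upstream
offset. Interval intersection itself (`intersect_ranges()`) exposes
standard bedtools-intersect semantics and is backed by `IRanges`; the
test suite checks it against a brute-force all-pairs oracle.

## Enrichment statistics

`fisher_2x2()` computes the two-sided Fisher exact p as the sum of
hypergeometric point probabilities not exceeding the observed table's
(the convention of standard exact tests), in log space so genome-scale
counts survive. For tables whose smallest expected cell exceeds
10<sup>4</sup> the exact sum is both expensive and indistinguishable
from the chi-squared approximation with continuity correction, which is
substituted with a message. No multiple-testing correction is applied
anywhere: the statistics mirror raw single-test reporting.

`enrichment_factor()` is the ratio of a focal percentage to the genomic
background percentage (e.g. percent of EST starts in pG4 over percent of
the genome in pG4). `overlap_enrichment()` builds the 2x2 table
`[[events in pG4, events outside], [pG4 bp, other bp]]`; mixing event
counts and base counts in one table is an assumption (the original
in-house construction is not printed anywhere), and the result carries a
note saying so.

## Expression statistics

Levels are compared on per-gene means of $\log_2(\mathrm{fpkm} + 1)$
(`log_mean_expression()`, Wilcoxon rank-sum via `group_compare()`).
Tumor/normal contrast is the per-gene
$\log_2((\bar x_T + 1)/(\bar x_N + 1))$ with a Welch t test between
gene sets — set sizes and variances differ widely, so equal variances
are not assumed.

Variability uses the coefficient of variation,
$100 \cdot \mathrm{SD}/\mathrm{mean}$:

* **indiv-CV** (`indiv_cv()`): per gene, across the individual samples
  of one condition.
* **g-CV** (`g_cv()`): per sample, across the genes of a set.

Both are computed on **linear** fpkm by default: the definition applies
to expression itself, and log transforms are a plotting device. Because
the linear-versus-log choice (and any zero-expression filtering) is not
standardized, both are surfaced as flags (`log_scale`; zero-mean units
are excluded and counted rather than silently dropped).
`paired_condition_test()` runs the two-sided paired t test on
tumor-minus-normal differences and refuses fewer than 15 complete pairs
— the cohort inclusion rule for paired comparisons. Zero-variance
non-zero differences are degenerate and flagged (`p = NA`) rather than
reported as infinitely significant.

## Mutations and structural impact

`intersect_mutations()` overlaps the affected reference span
(substituted bases; deleted span; insertion point) with hits.
Deduplication (`uniqueness_key()`) follows catalog semantics: germline
records are unique by genomic change, somatic records by change and
sample, so a recurrent somatic variant counts once per tumor sample.
`stability_stratify()` splits hits at Q-score ≥ 19 (boundary
inclusive); Q-scores are consumed as input — the scoring model behind
them is external and not reimplemented. `hotspot_rank()` orders pG4s by
unique mutation load (ties by coordinate) and separately tabulates
per-site recurrence of short indels.

`substitution_impact()` folds a pG4 extended by 20 bp flanks
(`extend_for_folding()`) in wild-type and mutant form through a folding
adapter and summarizes each as (minimum ΔG, maximum melting temperature,
structure count). Arrow conventions: Tm and structure count follow the
raw metric direction; the ΔG arrow is expressed as *stability*
direction, i.e. a mutant ΔG that is less negative by more than ε means
stability **down**. Published impact tables print the raw ΔG direction,
so `read_impact_table()` flips it into the stability arrow before
tallying; with that reading, `tally_impacts()` reproduces the published
14 / 15 / 15 / 31 counts over the 36 cardiac-gene substitutions shipped
in `inst/extdata`. Equality tolerances are ε = 0.01 kcal/mol for ΔG and
0.1 °C for Tm (the precision folding engines print); structure counts
compare exactly.

## The ΔG landscape

`bin_genome()` cuts chromosomes into 500-bp bins; bins containing `N`
and short terminal bins are excluded from scoring. `score_bins()`
records the minimum free energy an adapter reports per bin.
`dg_histogram()` uses left-closed 5 kcal/mol bins from −272.5 to
7.5 kcal/mol — a value exactly on an edge belongs to the bin starting
there (the convention is not standardized; this one is stated and
tested) — and clamps outliers into the end bins with a count.
`locate_hotspot()` maps an interval to its midpoint's bin and reports
the fraction of scored bins at least as stable (ΔG ≤ the bin's), so the
single most stable bin has percentile $1/n$ and the percentile is
monotone in ΔG.

The shipped `naive_fold()` adapter exists so this machinery runs and is
testable offline: it enumerates maximal Watson-Crick hairpin stems
(minimum loop 3), scores G:C pairs −3 and A:T pairs −2 kcal/mol plus a
+3 loop-initiation penalty, and assigns Wallace-rule melting
temperatures. It is deliberately simple, deterministic, and makes no
claim to thermodynamic accuracy; genome-scale ΔG summaries require a
real engine plugged into the same adapter interface, and the adapter
records engine and parameters as provenance.

## The synthetic generator

One root seed streams independent sub-seeds to the four components, so
identical configurations reproduce every output byte-for-byte and
components can be regenerated independently.

* **Genome** (`gen_genome()`): i.i.d. background at the configured GC
  content (default 0.41); canonical motifs (loops drawn from A/C/T so
  runs cannot extend) planted at non-overlapping positions until the
  target covered-base density — default 0.34%, the human genome-wide
  figure — is reached, counting spurious background motifs toward the
  target. A guard zone of `loop_max + 1` A/T bases around each planted
  motif prevents chaining into the flanks, which is what makes
  exact-coordinate recovery a fair test. Truth is annotated post hoc
  with the regex reference on both strands, so legitimate spurious
  motifs are part of the truth set.
* **Annotation** (`gen_annotation()`): non-overlapping multi-exon gene
  models (2–6 exons of 100–250 bp, introns 150–600 bp, the geometry
  averaging ≈2.4 kb per gene, hence the default of 30 genes per 100 kb);
  EST starts fall inside true pG4 intervals independently with
  probability `est_pg4_overlap` (default 0.63%, the human EST figure).
* **Expression** (`gen_expression()`): log-normal fpkm. Within-gene SD
  comes from the target CV via $\sigma = \sqrt{\log(1 + (c/100)^2)}$,
  so each gene's linear-scale CV equals its target in expectation
  (defaults 30% for the pG4 set, 60% for the rest). The pG4 set also
  has higher mean expression and smaller between-gene spread, which
  makes its g-CV lower. Tumors add a per-gene log2 shift (mean 0.5),
  widen within-gene SD by 1.1, and shrink each gene's *total* deviation
  from the set center by 0.8 for the pG4 set — shrinking the total
  deviation rather than only the baseline is essential, because an
  independent tumor shift would otherwise add between-gene variance and
  reverse the planted g-CV reduction.
* **Mutations** (`gen_mutations()`): uniform background over non-pG4
  bases with the in-pG4 per-base rate inflated by `pg4_fold`
  ($P(\text{in pG4}) = fq/(fq + 1 - q)$ for base fraction $q$), plus
  optional exact-recurrence indel hotspots with distinct sample ids.

What the generator does *not* emulate: isochore structure, repeats,
real gene architecture, expression correlation structure, or
sequencing noise. Passing closed-loop tests therefore demonstrates that
the statistics recover what was planted under their own model
assumptions — not that the biological claims hold on real data, which
requires the real inputs.

## Numerical choices and edge cases

* Fisher exact in log space; chi-squared with continuity correction
  above expected cell 10<sup>4</sup>.
* Exact Wilcoxon for small untied groups, tie-corrected normal
  approximation otherwise (base R behaviour); all-tied input returns
  p = 1 with a warning.
* CV excludes zero-mean units with a count; rescaling invariance is
  tested.
* Splice-profile argmax ties resolve to the most upstream offset;
  all-zero profiles flag undefined folds instead of dividing by zero.
* Histogram edges are left-closed; out-of-range ΔG values clamp into
  the end bins with a count.
* Unsorted intersection input is sorted internally with a message;
  malformed gene models fail naming the gene.

One caveat worth stating: with 5000 mutations at a pG4 base fraction of
0.34%, the expected in-pG4 count is only ≈17, so the exact Fisher
p-value is discrete (point masses up to ≈0.1) and conservative. Its
null distribution is therefore visibly non-uniform at this scale — a
property of exact tests on small expected counts, not an implementation
artifact; the fold estimate itself is unbiased, and the discreteness
fades at genome-scale counts where the chi-squared route engages.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic
data: 100 kb genomes, 30-gene annotations, 200 genes per set × 200
patient pairs for expression, 5000-mutation catalogs, 1000 random
sequences for the scanner/oracle comparison, and 100–200 replicate
loops for the distributional checks. The full suite completes in about
a minute and a half on one core.

## Worked example

```{r example}
cfg <- sim_config(seed = 1, chrom_lengths = c(chr1 = 30000L),
                  n_genes = 8L, n_ests = 500L,
                  expression = list(n_genes_per_set = 50L,
                                    n_patients = 30L),
                  mutation = list(n = 500L))
rep <- run_pipeline(cfg, splice_window = 200L)
rep$genome_stats[c("pg4_bp", "pg4_pct", "est_pct",
                   "est_enrichment_factor")]
rep$expression[c("indiv_cv_median", "gcv_paired_p", "gcv_direction")]
```

## Limitations

* The naive folder is a stand-in interface exerciser, not a
  thermodynamic model; ΔG landscape *values* are only meaningful with a
  real engine behind the adapter.
* Q-scores are external input; without them stability stratification
  degrades to a counted exclusion.
* The 2x2 construction for event-versus-base enrichment mixes units and
  is flagged in output.
* Synthetic data validates mechanics, not biology (see above).
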