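---
title: "Mapping X-linked recessive mutations from pooled hemizygous males: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping X-linked recessive mutations from pooled hemizygous males: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemimapper)
```

This vignette is the package's own account of the models it implements: the
genetic and sequencing assumptions behind the simulator, the two windowed
scan statistics and why they localize an X-linked recessive locus, the
variant-triage and indel-calling conventions, the exact tests, and the
numerical choices and limitations a user should know about.

## The mapping model

Consider a spontaneous recessive mutation on the X chromosome, first seen in
a single hemizygous male. Outcrossing him gives phenotypically wild-type F1s;
F1 carrier females outcrossed to unrelated males produce F2s of which one
quarter — all male — are mutant, because a male is affected exactly when his
single maternal X carries the mutant allele. Both Mendelian facts are exact
consequences of the transmission rules and are checked as exact properties in
the tests (mutant fraction converging to 1/4; mutant sex always male).

Pooling DNA from many mutant F2 males and sequencing the pool gives, at each
segregating site, allele counts whose expectation is governed by linkage to
the causative locus. Writing $r$ for the recombination fraction between a
marker and the locus, the probability that a pooled X carries the mutant
founder's allele at that marker is $1-r$: exactly 1 at the locus, decaying
toward 1/2 for unlinked markers. The package scans two statistics over a
sliding window of `window_size = 50` variants advancing `step = 5` at a time
(the window is counted in variants, not base pairs, so marker density does
not distort the track):

* **target-allele proportion** — the mean over window variants of the
  fraction of pooled reads matching the allele carried by the original
  mutant male (his genotype column defines the target allele at each site);
* **mixed-variant proportion** — the fraction of window variants whose
  pooled reads support two or more alleles. Around the causative locus all
  pooled haplotypes are identical by descent, so with error-free reads this
  statistic is *exactly* zero there, not merely small.

The window statistic is the mean of per-variant proportions rather than the
ratio of pooled read totals; the two differ only under depth heterogeneity,
and a `pooled_reads = TRUE` switch in `scan_bsa()` selects the read-total
variant. The peak is the window maximizing the target-allele proportion,
with ties broken by the lower mixed proportion and then the smaller start
index; peak calling by eye is replaced by this deterministic rule.

## What the simulator emulates

`simulate_founders()`, `cross_design()`, `simulate_f2_cohort()` and
`simulate_pooled_reads()` realize the pedigree above with these choices:

* **Recombination.** Crossover counts per marker interval are Poisson with
  mean $d/100$ for an interval of $d$ cM — the Haldane no-interference
  model, giving $r = \tfrac12(1 - e^{-2d})$ for $d$ in Morgans. The tests
  recover this closed form on two-locus designs within Monte-Carlo error.
  Positive crossover interference would only sharpen linkage relative to
  this model, so it is the conservative default.
* **Marker panel.** Founder haplotypes are generated so that marker sites
  are informative for the scan: the mutant male's X carries the alternate
  allele and the F0 female is homozygous reference — precisely the sites
  that survive the F0-subtraction filter. A configurable fraction of sites
  (`shared_frac`, default 0.3) instead carries the alternate allele in the
  F0 female; these exercise the subtraction filter and are removed by it,
  as shared population variation would be.
* **Read depths and errors.** Pooled depth per site is Poisson with mean
  `mean_depth` (default 12, the middle of a moderate 10–14x design). Each
  read draws its allele uniformly from the pooled X haplotypes and is
  corrupted to the other allele with probability `error_rate`. Because
  reads are i.i.d. given the pool allele frequency $q$, the alternate-read
  count is drawn as a single Binomial$(D,\, q(1-e) + (1-q)e)$ variate —
  exactly equivalent to per-read simulation, and fast. Sites are biallelic;
  the scan statistics are allele-count based, so biallelic sites suffice.
* **Quality.** Simulated records carry a constant QUAL of 60. In real data
  QUAL comes from an upstream caller (out of scope here — the pipeline
  starts from a VCF); the simulated value only needs to interact correctly
  with the strict `> 40` filter.
* **Seeds.** One integer seed fans out to named substreams (founders,
  cohort, reads), so each stage is independently reproducible and a fixed
  seed gives bit-identical VCF output; the pipeline manifest records MD5
  hashes to make this checkable.

Study sizes follow the design being emulated: `pool_size = 47` mutant males
from an F2 cohort of `n_f2 = 300` (expected 75 mutant males, so drawing 47
is comfortably feasible), six F1 carrier females mothering the cohort. Two
stock maps are provided: `map_uniform()` (500 markers over 100 cM — a
single fish chromosome's worth of genetic length) and `map_linked_block()`
(an 80-marker block at zero genetic distance around the causative site,
flanked by spaced markers). The linked block is deliberately wider than one
50-variant window so that, even after the depth filter removes the ~2% of
sites that Poisson(12) leaves under 6 reads, a full window of surviving
variants remains inside the block; that window's statistics are then exactly
(1.0, 0) at zero error.

What the simulator does **not** emulate: read mapping artifacts, indel
(mis)alignment, depth overdispersion beyond Poisson, caller-dependent QUAL
distributions, multi-chromosome genomes, and linkage disequilibrium in the
founder populations. Passing tests therefore demonstrate that the scan and
filters behave correctly on data with the assumed statistical structure —
not that any particular real dataset is free of those artifacts.

## Filters

`filter_variants()` applies the pre-scan rules with strict readings: QUAL
strictly greater than 40; at least 6 pooled reads covering the variant
("more than five"); and the alternate allele absent from the F0 female —
by default absent from both her genotype call and her allele depths, with
`exclude_mode` selecting either condition alone. The depth rule counts reads
in the pooled sample only. A multi-allelic record survives if any alternate
passes every rule. Filtering is idempotent, order-preserving, and monotone
in both thresholds; these invariants are property-tested on randomized
record sets.

## Variant triage

`classify_effect()` projects a variant onto a single-transcript gene model
(`gene_model()` validates the CDS: whole codons, start codon, terminal stop,
no internal stop). SNVs are synonymous, missense (scored with the embedded
BLOSUM62 matrix) or nonsense. Indels whose length change is not a multiple
of three are frameshifts; `codons_to_stop` counts the complete novel codons
strictly before the first premature stop in the shifted frame, so a stop
arriving as the eighth novel codon reports 7 — the convention is pinned by
constructed examples in the tests, including a synthetic CDS carrying a
heptaguanine run into which one more G is inserted. Homopolymer context is
reported because indel formation is elevated in long single-base runs, which
is the mechanistic suspicion for exactly such insertions.
`rank_candidates()` orders verdicts frameshift/nonsense, then missense with
negative BLOSUM62 score, then missense scoring ≥ 0, in-frame indels,
synonymous, noncoding — a deterministic rendering of "highest predicted
impact first". On minus-strand genes, alleles are reverse-complemented
before CDS projection; coordinates stay genomic. No real gene's CDS is
bundled; triage operates on whatever gene model and variants are supplied.

## Clone indel analysis

`align_clone()` performs end-to-end pairwise alignment under affine gap
scoring, defaulting to match +2, mismatch −3, gap open 10, gap extend 1 —
tuned for near-identical Sanger clones carrying few, possibly large, indels
(a 20 bp deletion costs 30, far less than 20 mismatches, so large indels
align as single gaps). Reverse-complemented clones are flipped
automatically. `call_indels()` turns each contiguous gap run into one call
and left-aligns indels within repeats (the VCF convention), making
coordinates reproducible. `classify_outcome()` distinguishes unedited
clones, local edits at a single cut site, intervening deletions spanning
both cut sites of a guide pair, and complex outcomes; the cut site is fixed
3 bp 5' of the PAM (standard SpCas9 blunt-cut geometry), and "near a cut"
defaults to a 10 bp radius. `efficiency_tally()` counts clones with at
least one near-cut indel and rounds the percentage to the nearest integer;
note that 8 edited of 9 is 88.9%, i.e. 89 under this rounding.

`compare_indel_sizes()` tests whether paired-guide clones carry larger
indels than single-guide clones, comparing absolute lengths with a
one-sided Mann-Whitney U. For combined samples of at most 12 the p-value is
computed by full enumeration of all group assignments (ties handled by
midranks), which is exact even with the heavy ties integer indel sizes
produce; larger samples use the tie-corrected normal approximation with
continuity correction. The enumeration is cross-checked in the tests
against an independent pairwise-counting oracle and, on tie-free data,
against the classical exact distribution.

## Exact count statistics

`binomial_exact_test()` and `fisher_exact_2x2()` are explicit tail and
hypergeometric-enumeration sums. Two-sided p-values use the small-p-values
(minimum-likelihood) convention — sum the probabilities of all outcomes no
more probable than the observed one, with a `1 + 1e-7` relative guard
against floating-point ties — matching the convention of standard
statistical software, against which both are cross-checked on random grids.
`compare_editing_rates()` addresses comparing two editing efficiencies when
only the two count pairs are known: the group-1 count is tested against the
group-2 rate taken as an exact binomial null. This is an interpretation —
with per-embryo outcome tables one would prefer Fisher's exact test — and
the method label records the construction. `tally_phenotypes()` returns raw
fractions; `format_pct()` renders them at whatever precision a report
prints (one decimal for segregation ratios like 24.6, integers for editing
summaries like 91).

## Numerical choices, degenerate inputs, tie-breaks

* Window indices are 0-based half-open internally; all reported coordinates
  are 1-based inclusive. Trailing partial windows are dropped; the window
  count is $\lfloor (n - W)/s \rfloor + 1$.
* Records where the target-defining sample is uncalled or heterozygous, or
  where the pool has zero depth, are skipped with a message and a count.
* "Mixed" requires each allele to be supported by at least `min_support`
  reads (default 1, the literal reading; raise it to guard against error
  reads when the error rate is material).
* Peak ties: lower mixed proportion, then smaller start index. Mann-Whitney
  enumeration compares $U \ge U_{obs}$ with a $10^{-9}$ slack so midrank
  halves never flip on floating-point representation.
* Degenerate guards: empty pools, empty groups, zero-trial nulls, and
  degenerate (0 or 1) null rates are errors, not silent results.

## Problem sizes used in the checks

The packaged checks simulate 500-marker chromosomes for peak recovery
(20 independent seeds) and a 200-marker linked-block design for the
exact-zero mixed-proportion property; the Mann-Whitney enumeration is
verified on 10,000 random small-sample cases. These sizes were chosen to
exercise the statistics at the scale of the emulated study design while
keeping the default test run fast on a single CPU.

## Known limitations

Single chromosome, biallelic sites, single-transcript gene models, no
FASTQ-level simulation, no significance envelope on the scan (the peak is
reported, not tested), no chromatogram deconvolution for mosaic Sanger
traces, and no multiple-testing machinery (none is needed for the handful
of planned tests the analysis makes).
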